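# Published summary statistics of the Phialocephala subalpina genome
# project used as worked-example inputs for ratio recomputation.
key	value
genome_size_mb	69.69
predicted_genes	20173
total_clusters	20555
focal_clusters	12932
total_interpro_accessions	6556
accessions_gt3x	386
accessions_overrepresented	963
est_mapped	28045
est_total	28092
cazyme_gene_models	881
cazyme_modules	998
hgt_candidate_genes	21
hgt_screened_genes	163
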