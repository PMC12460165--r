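# Default simulated cytokine-stimulation experiment (flat key-value format).
# One control, six reference cytokine conditions, five partial-agonist
# chimera conditions on a STAT3 attenuation grid; 3 replicates each.
n_genes = 2000
program_sizes = STAT1:200,STAT3:200,STAT5:200,STAT6:200
overlap_fraction = 0
frac_repressed = 0.3
effect_log2fc = 2
dispersion = 0.1
baseline_log2_mean = 6
baseline_log2_sd = 2
library_size_range = 0.7,1.3
n_replicates = 3
offtarget_fraction = 0.1
gene_length_range = 500,10000
seed = 1
condition = noICD|control||
condition = IFNa|reference|STAT1|STAT1:1
condition = IL10|reference|STAT3|STAT3:1
condition = IL21|reference|STAT3|STAT3:1
condition = IL2|reference|STAT5|STAT5:1
condition = IL7|reference|STAT5|STAT5:1
condition = IL4|reference|STAT6|STAT6:1
condition = chimera_a000|query||
condition = chimera_a025|query||STAT3:0.25
condition = chimera_a050|query||STAT3:0.5
condition = chimera_a075|query||STAT3:0.75
condition = chimera_a100|query||STAT3:1
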