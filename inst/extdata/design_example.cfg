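# Example barcode design configuration.
# One key per line; keys mirror the arguments of design_constraints().

length = 18
count = 500
gc_min = 0.45
gc_max = 0.65
max_homopolymer = 4
max_dimer_repeat = 3
max_trimer_repeat = 3
min_complexity = 0.5
self_hyb_tm_max = 50
cross_hyb_tm_max = 50
min_distance = 4
padding = 1
seed = 42

# Restriction sites to exclude (both strands are screened):
forbidden_motifs = GAATTC, GGATCC

# Primer/adapter sequences may also be supplied from FASTA files:
# primers_fasta = primers.fa
# motifs_fasta = sites.fa
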