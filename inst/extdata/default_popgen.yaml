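# Default DFE / demography / mutation configuration for the candidate-gene
# forward simulator.  The DFE approximates the published gamma fit for new
# non-synonymous mutations (point mass at neutrality plus a heavy-tailed
# gamma of deleterious magnitudes); the size history is an
# expansion-without-bottleneck approximation appropriate for an
# African-ancestry-majority cohort.  The mutation rate is the canonical
# human per-nucleotide rate.  See the methods vignette for the calibration
# targets these defaults reproduce and for what the 4Ns-rescaled runs
# truncate.
neutral_mass: 0.1
gamma_shape: 0.184
gamma_scale: 0.23      # mean deleterious |s| = shape * scale ~ 0.042
epochs:
  - duration: 2000     # ancestral equilibrium (burn-in is added on top)
    size: 8000
    growth: 0.0
  - duration: 1600     # recent exponential growth to ~20,000 diploids
    size: 8000
    growth: 0.00057274 # log(2.5)/1600
mutation_rate: 2.0e-08 # per site per generation
locus_length: 10200   # sites in the candidate region (gene plus flanks)
rescale_factor: 10     # 4Ns-preserving down-scaling for desk-scale runs
seed: 20260901
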