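# Point estimates for the doublesex-targeting sex-distorter gene drive.
# d_f, d_m are drive *transmission* fractions (the D share of a W/D
# heterozygote's gametes), estimated directly from the fraction of
# marker-positive progeny of heterozygous parents (0.999 females, 0.960
# males; the equivalent "homing rates" 2T-1 are 99.8% and 92%).
d_f: 0.999
d_m: 0.960
# Half of non-drive gametes from heterozygotes are repaired to the
# nonfunctional resistant allele R (representative end-joining fraction).
u_f: 0.5
u_m: 0.5
# Male progeny fraction of SDGD fathers (X-shredding); assayed 0.93,
# assumed equal for heterozygous and homozygous fathers.
m: 0.93
# Reproductive fitness by target-site class, relative to wild type.
# Females: drive heterozygotes at 0.627 (reduced larval output); females
# without a functional target-gene copy (DD, DR, RR) are sterile.
female_fitness:
  WD: 0.627
  DD: 0
  DR: 0
  RR: 0
# Males carrying the construct share the assayed SDGD male fitness 0.854.
male_fitness:
  WD: 0.854
  DD: 0.854
  DR: 0.854
# Baseline: no fitness cost from carrying a damaged X chromosome.
s_X_f: 0
s_X_m: 0
h_X_f: 0.5
# Intrinsic growth rate per generation at low density (continuous model).
R_m: 6
# Cage demography: 600-larva bottleneck; wild-type larval output of 140.8
# per female decomposed as 165.6 eggs x 0.85 hatch.
cage:
  larva_cap: 600
  mean_eggs: 165.6
  hatch_wt: 0.85
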