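# Scenario registry: named genotype x condition combinations reproducing
# the bioenergetic schemes and resting-cell experiments.  Rationals are
# written as "p/q" strings.
schema_version: 1

genotypes:
  wild_type:
    hydABC_present: true
    hdcr_hydrogenase_module_present: true
    hdcr_fdh_module_present: true
    fd_hdcr_enabled: false
    cooS_present: true
    rnf_present: true
    label: "wild type"
  hydrogenase_free_mutant:
    hydABC_present: false
    hdcr_hydrogenase_module_present: false
    hdcr_fdh_module_present: true
    fd_hdcr_enabled: true
    cooS_present: true
    rnf_present: true
    label: "CO-adapted hydrogenase-free mutant (Fd-mode HDCR)"

conditions:
  h2_co2:
    substrates_available: [H2, CO2]
    label: "H2 + CO2, bicarbonate-buffered"
  co:
    substrates_available: [CO]
    label: "CO as sole carbon and energy source"
  formate:
    substrates_available: [formate]
    label: "formate, phosphate-buffered"
  fructose:
    substrates_available: [fructose]
    label: "20 mM fructose"
  co_na_depleted:
    substrates_available: [CO]
    na_available: false
    label: "CO, Na+-depleted resting cells"
  co_uncoupled:
    substrates_available: [CO]
    atp_coupling_available: false
    label: "CO, 300 mM bicarbonate (ATP-uncoupled) resting cells"

scenarios:
  wt_h2co2:
    genotype: wild_type
    condition: h2_co2
    product: acetate
    notes: >
      Autotrophic reference state: HydABC bifurcation feeds Fd and NADH,
      H2-mode HDCR reduces CO2 to formate.  Expected ATP yield 10/33
      (reported 0.3).
  wt_co:
    genotype: wild_type
    condition: co
    product: acetate
    notes: >
      Calculated wild-type CO scheme.  Stoichiometrically solvable (yield
      50/33, reported 1.5) although the wild type does not actually grow on
      CO; CO toxicity is not modelled.
  wt_formate:
    genotype: wild_type
    condition: formate
    product: acetate
    notes: >
      Three-quarters of the formate is oxidised back to H2 + CO2 by the
      HDCR; 0.5 Fd2- reaches Rnf per acetate; yield 10/33 (reported 0.3).
  mut_co:
    genotype: hydrogenase_free_mutant
    condition: co
    product: acetate
    notes: >
      CO-adapted mutant on CO: ferredoxin-mode HDCR replaces the H2 loop;
      yield 40/33 (reported 1.2).
  mut_formate:
    genotype: hydrogenase_free_mutant
    condition: formate
    product: acetate
    notes: >
      Mutant on formate: all reducing equivalents reach Rnf as Fd2-;
      yield 40/33 (reported 1.2), a 300% increase over the wild type.
  mut_h2co2:
    genotype: hydrogenase_free_mutant
    condition: h2_co2
    product: acetate
    notes: >
      No H2-oxidising reaction remains; expected infeasible (the mutant
      does not grow on H2 + CO2).
  mut_fructose:
    genotype: hydrogenase_free_mutant
    condition: fructose
    product: acetate
    notes: >
      Heterotrophic control: glycolytic Fd2- and NADH exactly cover the
      Wood-Ljungdahl demand via the Fd-mode HDCR (homoacetogenesis,
      fructose:acetate 1:3).
  resting_na_depleted_co:
    genotype: hydrogenase_free_mutant
    condition: co_na_depleted
    product: formate
    notes: >
      Without Na+ the Rnf complex and ATP synthase are absent; CO is
      oxidised by CooS and the CO2 re-reduced to formate by the Fd-mode
      HDCR.  CO:formate 1:1 (measured 1.1:1).
  resting_uncoupled_co:
    genotype: hydrogenase_free_mutant
    condition: co_uncoupled
    product: formate
    notes: >
      High bicarbonate depletes ATP so the formyl-THF synthetase cannot
      run; the methyl branch is dead and only formate is formed.
      CO:formate 1:1 (measured 1.1:1).
  resting_mixed_co:
    genotype: hydrogenase_free_mutant
    condition: co
    product: acetate
    phi: "1/2"
    notes: >
      Resting cells with 60 mM bicarbonate form acetate and formate
      side by side; the split is not fixed by stoichiometry and is exposed
      as the formate branch fraction phi (default 1/2, matching the
      near-equimolar endpoint).  At phi = 1/2, CO:acetate:formate = 5:1:1.
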