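# Built-in model configuration: US 2011 payer-perspective parameterization
# of the short-term GDM / maternal-overweight / macrosomia cost model.
# Probabilities may be written as proportions or as "x%" strings; both are
# normalized to proportions at load time.
schema_version: 1
cost_year: 2011
currency: USD

# Perinatal complication probabilities per pregnancy arm. Keys are the
# canonical cost-item names of the cost table below (outcome names from the
# source trials are mapped onto them via the package's documented alias
# table). Mild-GDM arms: Landon trial (intervention = treated, control =
# untreated), plus brachial plexus injury (Ohno) and the hydramnion /
# stillbirth add-ons reported for GDM only (Michlin/Hod). Obese /
# non-obese arms: Salihu cohort.
probabilities:
  gdm_treated:
    Child_hypoglycemia: "16.30%"
    Child_hyperbili: "9.60%"
    Child_macrosomia: "5.90%"
    Child_pretermdelivery: "9.40%"
    Child_NICU: "9.00%"
    Child_resp_distress: "1.90%"
    Child_brachplexus: "6.70%"
    Mother_induction: "27.30%"
    Mother_cesarean: "26.90%"
    Mother_shoulder: "1.50%"
    Mother_pre_eclampsia: "2.50%"
    Mother_hydramnion: "0.60%"
    Mother_still_birth: "0.40%"
  gdm_untreated:
    Child_hypoglycemia: "15.40%"
    Child_hyperbili: "12.90%"
    Child_macrosomia: "14.30%"
    Child_pretermdelivery: "11.60%"
    Child_NICU: "11.60%"
    Child_resp_distress: "2.90%"
    Child_brachplexus: "6.70%"
    Mother_induction: "26.80%"
    Mother_cesarean: "33.80%"
    Mother_shoulder: "4.00%"
    Mother_pre_eclampsia: "5.50%"
    Mother_hydramnion: "0.60%"
    Mother_still_birth: "0.40%"
  obese:
    Mother_anemia: "1.31%"
    Mother_gdm: "3.08%"          # insulin-treated diabetes
    Mother_gest: "7.18%"         # other (diet-treated) diabetes
    Mother_hypertension: "2.23%" # chronic hypertension
    Mother_pre_eclampsia: "5.89%"
    Mother_PIH: "0.08%"          # eclampsia
  non_obese:
    Mother_anemia: "1.18%"
    Mother_gdm: "0.83%"
    Mother_gest: "2.18%"
    Mother_hypertension: "0.28%"
    Mother_pre_eclampsia: "2.42%"
    Mother_PIH: "0.06%"
  normal: {}

# Statistical-significance flags for the treated-vs-untreated (GDM) and
# obese-vs-non-obese contrasts; stored as metadata only. Non-significant
# differences still enter the model as point estimates.
significance:
  gdm:
    Child_hypoglycemia: NS
    Child_hyperbili: NS
    Child_macrosomia: S
    Child_pretermdelivery: NS
    Child_NICU: NS
    Child_resp_distress: NS
    Mother_induction: NS
    Mother_cesarean: S
    Mother_shoulder: S
    Mother_pre_eclampsia: S
  obese:
    Mother_anemia: NS
    Mother_gdm: S
    Mother_gest: S
    Mother_hypertension: S
    Mother_pre_eclampsia: S
    Mother_PIH: NS

# Unit costs (USD, 2011). Zero-cost items are deliberate: the events are
# tracked but carry no incremental payer cost in the source data.
costs:
  routine_normal_cost: 7790
  entries:
    Child_brachplexus: 1757
    Child_hyperbili: 2006
    Child_hypoglycemia: 2419
    Comp_child_IUFD: 82361
    Mp_child_IUGR: 15065
    Child_macrosomia: 4014
    Child_NICU: 15065
    Child_overweight: 4014
    Child_premature: 3376
    Child_pretermdelivery: 3376
    Child_resp_distress: 3376
    Child_shoulder: 1757
    Mother_anemia: 0
    Mother_bodymass: 0
    Mother_cesarean: 4189
    Mother_episiotomy: 5165
    Mother_gdm: 1786
    Mother_gest: 1786
    Mother_gesthyper: 1786
    Mother_hydramnion: 0
    Mother_hypertension: 1786
    Mother_induction: 5165
    Mother_PIH: 19184
    Mother_pre_eclampsia: 19184
    Mother_PROM: 5165
    Mother_shoulder: 950
    Mother_still_birth: 0
    Mother_weight_gain: 0

# Treatment-effect odds ratios for macrosomia / LGA. Shipped for opt-in
# use via or_to_probability(); NOT applied in the base case (the
# probability tables above already distinguish treated vs untreated).
odds_ratios:
  - outcome: macrosomia
    comparison: "treatment GDM vs. usual care"
    odds_ratio: 0.38
    ci_low: 0.30
    ci_high: 0.49
    source: Horvath
  - outcome: macrosomia
    comparison: "no treatment GDM vs. control"
    odds_ratio: 2.66
    ci_low: 1.93
    ci_high: 3.67
    source: Langer
  - outcome: macrosomia
    comparison: "treatment vs. control"
    odds_ratio: 1.13
    ci_low: 0.82
    ci_high: 1.55
    source: Langer
  - outcome: lga
    comparison: "no treatment GDM vs. control"
    odds_ratio: 3.28
    ci_low: 2.53
    ci_high: 3.67
    source: Langer
  - outcome: lga
    comparison: "treatment GDM vs. control"
    odds_ratio: 1.06
    ci_low: 0.81
    ci_high: 1.38
    source: Langer

# Delivery-strategy outcome probabilities for an estimated fetal weight of
# 4500 g (Herbst decision analysis).
strategies:
  elective_induction:
    cesarean_delivery: "35%"
    shoulder_dystocia_cesarean: "0.3%"
    shoulder_dystocia_vaginal: "14.5%"
  elective_cesarean:
    shoulder_dystocia: "0.1%"
  expectant:
    cesarean_delivery: "33%"
    shoulder_dystocia_cesarean: "0.3%"
    shoulder_dystocia_vaginal: "3%"
    plexus_injury: "18%"
    permanent_injury: "6.7%"

# US national demographics for the budget-impact translation.
population:
  population_size: 313847500
  pregnancy_rate_per_1000: 13.68
  condition_incidence: "5.5%"

# Printed per-case base-case cost breakdowns (calibration targets for the
# default "calibrated" arm mode).
calibration:
  normal:
    mother: 7790
    child: 0
  gdm:
    mother: 11794
    child: 3799
  overweight:
    mother: 13047
    child: 5243

# Optional switches, off by default.
overrides:
  # Naylor reports a much higher shoulder-dystocia probability than the
  # Landon control arm's 4.0%; kept available but not applied.
  shoulder_dystocia:
    probability: "14.5%"
    applied: false
  # Combined "preeclampsia OR gestational hypertension" column; metadata
  # only (would double-count the plain preeclampsia entries above).
  preeclampsia_or_gesthyper:
    gdm_treated: "8.60%"
    gdm_untreated: "13.60%"

# Perinatal mortality attributable to (un)treated GDM: no published point
# value is carried in the cost sources, so it defaults to zero.
mortality_probability: 0
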