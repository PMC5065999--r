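# Intervention arm: adalimumab readily available; the cohort starts in the
# induction state (160 mg / 80 mg / 40 mg every other week) and responders
# follow the real-life maintenance-of-response curve. Probabilities are
# stored in percent exactly as printed; "#" rows are the complement entries.
# Chronic-pouchitis patients in this arm were previously exposed to (and
# failed) adalimumab, so the pouchitis response curve carries the 15%
# response discount and the pouchitis complication row is the "ADA
# available" variant.
name: uc_ada
cycle_length_years: 0.25
annual_discount_rate: 0.05
horizon_cycles: 40

initial_distribution:
  ada_induction: 1.0

retention_series:
  uc_maintenance:
    # adalimumab maintenance-of-response, UC real-life cohort; plateau >= cycle 20
    values: [86.8, 73.3, 66.5, 62.0, 58.7, 56.2, 54.1, 52.4, 50.9, 49.6,
             48.5, 47.5, 46.5, 45.7, 45.0, 44.3, 43.6, 43.0, 42.4, 41.9, 41.4]
  cp_response:
    # chronic pouchitis on adalimumab, previously exposed patients
    # (anti-TNF-naive curve reduced by 15%, rounded to one decimal)
    values: [53.2, 52.0, 50.9, 49.8, 48.7, 47.7, 46.7, 45.6, 44.6, 43.7,
             42.8, 41.8, 40.9, 40.0, 39.1, 38.3, 37.4, 36.6, 35.8, 35.0, 34.2]
  dose_escalated:
    # maintenance after dose escalation (Crohn's disease outpatient data)
    values: [93.8, 80.5, 73.7, 69.1, 65.8, 63.2, 61.1, 59.4, 57.8, 56.5,
             55.3, 54.3, 53.3, 52.5, 51.7, 51.0, 50.3, 49.7, 49.1, 48.5, 48.0]

states:
  - {id: ongoing_steroids, label: "Ongoing steroids",
     cost_per_cycle: 917, cost_rel_halfwidth: 0.25,
     annual_utility: 0.32, utility_halfwidth: 0.31}
  - {id: steroid_response, label: "Response to steroids",
     cost_per_cycle: 0, cost_rel_halfwidth: 0.25,
     annual_utility: 0.79, utility_halfwidth: 0.21}
  - {id: unwell_steroids, label: "Unwell on steroids",
     cost_per_cycle: 917, cost_rel_halfwidth: 0.25,
     annual_utility: 0.32, utility_halfwidth: 0.31}
  - {id: steroid_complication, label: "Steroid complication",
     cost_per_cycle: 23919, cost_rel_halfwidth: 0.25,
     annual_utility: 0.16, utility_halfwidth: 0.16}
  - {id: surgery, label: "Surgery (proctocolectomy with IPAA)",
     cost_per_cycle: 37159, cost_rel_halfwidth: 0.25,
     annual_utility: 0.16, utility_halfwidth: 0.16}
  - {id: surgery_response, label: "Response to surgery",
     cost_per_cycle: 0, cost_rel_halfwidth: 0.25,
     annual_utility: 0.58, utility_halfwidth: 0.15}
  - {id: chronic_pouchitis, label: "Chronic pouchitis",
     cost_per_cycle: 8144, cost_rel_halfwidth: 0.25,
     annual_utility: 0.32, utility_halfwidth: 0.31}
  - {id: surgical_complication, label: "Surgical complication",
     cost_per_cycle: 17586, cost_rel_halfwidth: 0.25,
     annual_utility: 0.49, utility_halfwidth: 0.32}
  - {id: ada_induction, label: "Adalimumab (induction)",
     cost_per_cycle: 8144, cost_rel_halfwidth: 0.25,
     annual_utility: 0.32, utility_halfwidth: 0.31}
  - {id: ada_response, label: "Response to adalimumab",
     cost_per_cycle: 4442, cost_rel_halfwidth: 0.25,
     annual_utility: 0.79, utility_halfwidth: 0.21}
  - {id: ada_complication, label: "Adalimumab complication",
     cost_per_cycle: 12059, cost_rel_halfwidth: 0.25,
     annual_utility: 0.16, utility_halfwidth: 0.16}
  - {id: cp_ada_response, label: "Response to adalimumab (pouchitis)",
     cost_per_cycle: 4442, cost_rel_halfwidth: 0.25,
     annual_utility: 0.58, utility_halfwidth: 0.15}
  - {id: cp_unwell, label: "Unwell (pouchitis)",
     cost_per_cycle: 917, cost_rel_halfwidth: 0.25,
     annual_utility: 0.32, utility_halfwidth: 0.31}
  - {id: cp_ada_complication, label: "Adalimumab complication (pouchitis)",
     cost_per_cycle: 12059, cost_rel_halfwidth: 0.25,
     annual_utility: 0.16, utility_halfwidth: 0.16}
  - {id: cp_surgery, label: "Surgery (permanent ileostomy)",
     cost_per_cycle: 37159, cost_rel_halfwidth: 0.25,
     annual_utility: 0.16, utility_halfwidth: 0.16}
  - {id: cp_steroid_complication, label: "Steroid complication (pouchitis)",
     cost_per_cycle: 23919, cost_rel_halfwidth: 0.25,
     annual_utility: 0.16, utility_halfwidth: 0.16}
  - {id: cp_surgery_response, label: "Response to surgery (ileostomy)",
     cost_per_cycle: 0, cost_rel_halfwidth: 0.25,
     annual_utility: 0.44, utility_halfwidth: 0.11}
  - {id: cp_surgical_complication, label: "Surgical complication (ileostomy)",
     cost_per_cycle: 17586, cost_rel_halfwidth: 0.25,
     annual_utility: 0.37, utility_halfwidth: 0.24}
  - {id: death, label: "Death", cost_per_cycle: 0, annual_utility: 0,
     is_death: true}

transitions:
  - from: ongoing_steroids
    entries:
      - {to: steroid_response, p: 33.92, ci: [28.09, 40.33]}
      - {to: unwell_steroids, p: 57.11, ci: [50.5, 63.27]}
      - {to: steroid_complication, p: 2.80, ci: [0.56, 7.63]}
      - {to: surgery, complement: true}
  - from: steroid_response
    entries:
      - {to: steroid_response, p: 53.30, ci: [46.81, 59.67]}
      - {to: ongoing_steroids, complement: true}
  - from: unwell_steroids
    entries:
      - {to: steroid_complication, p: 2.80, ci: [0.56, 7.63]}
      - {to: surgery, p: 10.00, ci: [6.40, 14.28]}
      - {to: unwell_steroids, complement: true}
  - from: steroid_complication
    entries:
      - {to: surgery, p: 98.00, ci: [93.70, 99.78]}
      - {to: death, complement: true}
  - from: surgery
    entries:
      - {to: surgical_complication, p: 12.8, ci: [8.76, 17.91]}
      - {to: death, p: 2.50, ci: [0.98, 5.69]}
      - {to: surgery_response, complement: true}
  - from: surgery_response
    entries:
      - {to: surgery_response, p: 85.80}
      - {to: chronic_pouchitis, p: 11.70}
      - {to: surgical_complication, complement: true}
  - from: chronic_pouchitis
    entries:
      - {to: cp_ada_response, p: 53.2}     # cycle-0 value of cp_response
      - {to: cp_ada_complication, p: 4.20}
      - {to: cp_unwell, complement: true}
  - from: surgical_complication
    entries:
      - {to: surgery_response, p: 99.50, ci: [97.22, 99.99]}
      - {to: death, complement: true}
  - from: ada_induction
    entries:
      - {to: ada_response, p: 86.80, ci: [75.74, 97.86]}
      - {to: ada_complication, p: 3.04}
      - {to: unwell_steroids, complement: true}
  - from: ada_response
    entries:
      - {to: ada_response, series: uc_maintenance, index: cycle, mode: direct}
      - {to: ada_complication, p: 7.88}
      - {to: unwell_steroids, complement: true}
  - from: ada_complication
    entries:
      - {to: ada_response, p: 70.00}
      - {to: unwell_steroids, p: 14.00}
      - {to: surgery, p: 14.00}
      - {to: death, complement: true}
  - from: cp_ada_response
    residence_clock: true
    entries:
      # offset 1: cycle 0 of the curve was consumed by the entry transition
      # from the chronic-pouchitis state
      - {to: cp_ada_response, series: cp_response, index: residence,
         offset: 1, mode: direct}
      - {to: cp_ada_complication, p: 4.20}
      - {to: cp_unwell, complement: true}
  - from: cp_unwell
    entries:
      - {to: cp_surgery, p: 10.00}
      - {to: cp_steroid_complication, p: 2.80}
      - {to: cp_unwell, complement: true}
  - from: cp_ada_complication
    entries:
      - {to: cp_ada_response, p: 51.00}
      - {to: cp_unwell, p: 23.50}
      - {to: cp_surgery, p: 23.50}
      - {to: death, complement: true}
  - from: cp_surgery
    entries:
      - {to: cp_surgical_complication, p: 12.80}
      - {to: death, p: 2.50}
      - {to: cp_surgery_response, complement: true}
  - from: cp_steroid_complication
    entries:
      - {to: cp_surgery, p: 98.00}
      - {to: death, complement: true}
  - from: cp_surgery_response
    entries:
      - {to: cp_surgical_complication, p: 2.50}
      - {to: cp_surgery_response, complement: true}
  - from: cp_surgical_complication
    entries:
      - {to: death, p: 0.50}
      - {to: cp_surgery_response, complement: true}
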