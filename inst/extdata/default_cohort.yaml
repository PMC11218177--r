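# Default paired-foci cohort fixture: 10 patients (6 multicentric-like,
# 4 metastatic-like). Shared-fraction targets sit inside the 0-2.7% (MC)
# and 58-67.6% (ME) bands; cluster counts include the monoclonal foci
# (MC01 focus B, MC04 both foci). Germline totals have equal group means;
# immune counts separate the groups. Fields not listed per patient take
# the documented defaults (200 somatic SNVs/focus, purity 0.8, 8 CNV
# genes/focus, 30 SVs/focus, 2 LOH regions/focus with 2 planted
# partner-unique variants each).
base_seed: 20240701
depth:
  tumor_mean: 50
  normal_mean: 30
hq_min_alt: 3
patients:
  - id: MC01
    origin_model: MC
    target_shared_snv_fraction: 0.000
    n_clusters_per_focus: [2, 1]
    germline: {n_total: 58, n_immune: 9}
  - id: MC02
    origin_model: MC
    target_shared_snv_fraction: 0.004
    n_clusters_per_focus: [2, 2]
    germline: {n_total: 62, n_immune: 11}
  - id: MC03
    origin_model: MC
    target_shared_snv_fraction: 0.009
    n_clusters_per_focus: [2, 3]
    germline: {n_total: 60, n_immune: 10}
  - id: MC04
    origin_model: MC
    target_shared_snv_fraction: 0.013
    n_clusters_per_focus: [1, 1]
    n_cnv_per_focus: [8, 2]
    n_cnv_shared: 2
    germline: {n_total: 59, n_immune: 12}
  - id: MC05
    origin_model: MC
    target_shared_snv_fraction: 0.018
    n_clusters_per_focus: [3, 2]
    germline: {n_total: 61, n_immune: 13}
  - id: MC06
    origin_model: MC
    target_shared_snv_fraction: 0.024
    n_clusters_per_focus: [2, 2]
    germline: {n_total: 60, n_immune: 8}
  - id: ME01
    origin_model: ME
    target_shared_snv_fraction: 0.580
    germline: {n_total: 60, n_immune: 3}
  - id: ME02
    origin_model: ME
    target_shared_snv_fraction: 0.610
    germline: {n_total: 59, n_immune: 4}
  - id: ME03
    origin_model: ME
    target_shared_snv_fraction: 0.650
    germline: {n_total: 61, n_immune: 2}
  - id: ME04
    origin_model: ME
    target_shared_snv_fraction: 0.676
    germline: {n_total: 60, n_immune: 5}
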