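# Default model configuration (version 1).
#
# Volume/flow rules are fractions of body weight (1 kg/L density assumed) and
# of cardiac output; sex-averaged reference-child physiology. Partition
# coefficients are tissue:plasma equilibrium ratios for fluoride; bone is the
# depot tissue and carries a large partition coefficient. The reference adult
# plasma clearance (scaled to children by BW^0.75) and the daily urine
# volumes are calibration-sensitive entries: urinary concentrations reported
# by the pipeline scale directly with 1/daily_urine_volume.
version: 1
reference_clearance:
  value_L_min: 0.07        # adult fluoride plasma clearance
  reference_bw_kg: 70
cardiac_output_rule:
  coefficient_L_min: 0.235 # CO = coefficient * BW^exponent
  exponent: 0.75
blood_volume_fraction_bw: 0.08
compartments:
  - name: liver
    volume_fraction_bw: 0.026
    flow_fraction_co: 0.25
    partition_coefficient: 0.85
  - name: kidney
    volume_fraction_bw: 0.005
    flow_fraction_co: 0.19
    partition_coefficient: 1.2
  - name: bone
    volume_fraction_bw: 0.04
    flow_fraction_co: 0.05
    partition_coefficient: 250
  - name: rest_of_body
    volume_fraction_bw: 0.60
    flow_fraction_co: 0.51
    partition_coefficient: 0.5
daily_urine_volume_by_age:     # calibration-sensitive
  - age_years: 4
    volume_L_day: 0.5
  - age_years: 8
    volume_L_day: 0.7
# Bone handling: "equilibrating" = exchangeable bone pool, uptake
# CL_bone * (C_art - C_bone/P_bone), capacity set by the partition
# coefficient; "sink" = irreversible uptake CL_bone * C_art.
bone_mode: equilibrating
# Concentration driving renal elimination: "arterial" or "kidney_exit".
renal_driver: arterial
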