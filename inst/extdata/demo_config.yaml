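# Demo configuration: 10 synthetic subjects on a coarse grid; completes in a
# few minutes on one CPU. All tunables of the analysis are surfaced here.
n_subjects: 10
grid_dim: [96, 96, 40]
grid_spacing: [1.5, 1.5, 2.5]
lesions_per_subject: 4
lesion_hu_range: [150, 500]
lesion_size_range: [2, 4]
noise_sd: 5
validation_margin: 1.5
seed: 1
tracking:
  step_deg: 2
  span_deg: 240
  hu_tol: 25
  growth_mm: 0.25
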