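lesions:
- id: S3
  battery: sphere
  spec:
    shape_kind: sphere
    size: 17.0
    pattern: two_level
    tbr: 4.0
    centre:
    - 0.0
    - 0.0
    - 0.0
    shape_seed: 1
    inner_fraction: 0.5
    core_fraction: 0.4
    smooth_fwhm_mm: ~
- id: spheroid_necrotic
  battery: lesion
  spec:
    shape_kind: spheroid
    size: 11.0
    pattern: necrotic
    tbr: 4.0
    centre:
    - 0.0
    - 0.0
    - 0.0
    shape_seed: 1
    inner_fraction: 0.5
    core_fraction: 0.4
    smooth_fwhm_mm: ~
pet_spacing:
- 2.73
- 2.73
- 3.27
psf_fwhm_mm: 6.4
noise_scale: 500.0
noise_seeds:
- 1
- 2
- 3
noiseless: no
methods_sphere:
- AT
- RG
- GCM2
- GCM3
- GCM4
- GCM5
- GCM6
- GCM7
- GCM8
- WT
methods_lesion:
- AT
- RG
- GCM2
- GCM3
- GCM4
- GCM5
- GCM6
- WT
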