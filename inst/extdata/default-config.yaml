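# Default ctffr pipeline configuration.
# Units: mm for geometry and spacing, HU-like arbitrary units for intensity,
# kg/m^3 and Pa.s for the fluid, mmHg for pressures, mL/s for flow.
seed: 1
outdir: "ctffr-run"
phantom:
  L: 30.0          # vessel length
  R0: 2.0          # baseline lumen radius
  d: 0.5           # fractional diameter reduction at the throat
  s0: 15.0         # stenosis center
  w: 3.0           # Gaussian stenosis width (sd)
  spacing: 0.4     # isotropic voxel spacing
  lumen: 400.0     # contrast-enhanced lumen intensity
  background: 50.0 # soft-tissue background intensity
  noise_sd: 20.0   # additive Gaussian noise sd
  margin: 2.0      # transverse padding around the vessel
  supersample: 1   # 1 = hard voxel-center classification
segmentation:
  step: 1          # threshold scan step (intensity units)
  connectivity: 26 # for the largest-component cleanup
reconstruction:
  isolevel: 0.5
  pre_smooth: 0          # box-smoothing rounds before surfacing
  smooth_iterations: 0   # Laplacian smoothing of the mesh
  smooth_factor: 0.5
hemodynamics:
  rho: 1060.0            # blood density
  mu: 0.0035             # blood dynamic viscosity
  p_aortic_mmhg: 100.0   # mean aortic pressure Pr
  hyperemia: "flow"      # "flow" (prescribed hyperemic flow) or "resistance"
  rest_flow_ml_s: 1.0
  hyper_factor: 3.0      # hyperemic flow = factor x resting flow
  distal_resistance: 12.0 # mmHg/(mL/s), used when hyperemia: "resistance"
cohort:
  n: 90
  r_target:
    tc: 0.234
    tg: 0.237
    ldl: 0.285
    apo: 0.298
  event_prob:
    low: 0.1
    medium: 0.1
    high: 0.4
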