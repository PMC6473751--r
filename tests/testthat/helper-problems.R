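# shared reference problems: 1 mm slab, stiff-gel diffusivity, CYGGGYC kinetics
ref_slab <- function(C0 = 1, D = stiffsim_constants()$D_gel_stiff)
  slab_problem(1e-3, D, C0)

ref_kinetics <- function() tyrosinase_kinetics("cygggyc")

# coarse grid adequate for sub-1e-3 transport accuracy in tests
coarse_grid <- function(horizon) grid1d(dx = 2e-5, dt = 10, horizon = horizon)

mbth_substrate_levels <- c(0.25, 0.5, 1, 2, 4, 6, 8, 10)
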