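# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

default_patient <- function() fixture("patient", function() {
  generate_patient(patient_spec())
})

symmetric_patient <- function() fixture("sym_patient", function() {
  generate_patient(patient_spec(mt_cobb_deg = 0, tll_cobb_deg = 0,
                                avr_mt_deg = 0, avr_tll_deg = 0))
})

calibrated_model <- function() fixture("cal_model", function() {
  calibrate_standing(assemble_model(default_patient()))
})

calibrated_symmetric_model <- function() fixture("cal_sym_model", function() {
  calibrate_standing(assemble_model(symmetric_patient()))
})

initial_brace_fixture <- function() fixture("brace0", function() {
  model <- calibrated_model()
  oc <- find_max_overcorrection(model)
  bp <- trim_initial_brace(oc$deformed_skin,
                           trim_profile_default(model$anatomy))
  grid <- build_patch_grid(bp)
  list(oc = oc, bp = bp, grid = grid,
       smoother = smoothing_operator(bp, grid))
})

# a straight uniform vertical cantilever built from the package's frame
# elements, used as a closed-form beam oracle
cantilever_model <- function(nseg = 10, L = 300, EI = 2.9e6, EA = 1.35e6,
                             GJ = 2.9e6) {
  nodes <- cbind(0, 0, seq(0, L, length.out = nseg + 1))
  els <- lapply(seq_len(nseg), function(i)
    list(type = "frame", role = "disk", level = i, n1 = i, n2 = i + 1,
         EA = EA, EI = EI, GJ = GJ))
  structure(list(nodes = nodes, n_nodes = nseg + 1L, ndof = 6L * (nseg + 1L),
                 elements = els, masses = numeric(nseg + 1),
                 params = model_params_default(),
                 idx_skin = matrix(integer(0), 0, 0)),
            class = "trunk_model")
}
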