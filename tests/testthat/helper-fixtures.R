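# Shared fixtures, built once per test run and cached in this environment.
# Everything is generated in code under fixed seeds; no binary files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_env)) assign(name, build(), .fixture_env)
  get(name, .fixture_env)
}

# 200 s single-channel record alternating NSR and AF, preprocessed at 500 Hz
fix_mixed_record <- function() {
  fixture("mixed_record", function() {
    plan <- rhythm_plan(c(40, 50, 30, 40, 40),
                        c("NSR", "AF", "NSR", "AF", "NSR"),
                        patient_id = "fixmix")
    preprocess_record(generate_record(plan, seed = 101L))
  })
}

# 80 s pure-NSR record, preprocessed
fix_nsr_record <- function() {
  fixture("nsr_record", function() {
    preprocess_record(generate_record(
      rhythm_plan(80, "NSR", patient_id = "fixnsr"), seed = 202L))
  })
}

# small trained network on a linearly separable two-level ECM dataset
separable_ecm_dataset <- function(n_per_class = 60, seed = 7L) {
  px <- array(0, c(10, 219, 2 * n_per_class))
  set.seed(seed)
  for (i in seq_len(n_per_class)) {
    px[, , i] <- 0.5 + matrix(rnorm(2190, sd = 0.02), 10, 219)
    px[, , n_per_class + i] <- -0.5 + matrix(rnorm(2190, sd = 0.02), 10, 219)
  }
  meta <- tibble::tibble(
    window_id = sprintf("w%03d", seq_len(2 * n_per_class)),
    label = rep(c("AF", "NONAF"), each = n_per_class),
    patient_id = rep(c("pa", "pb"), each = n_per_class)
  )
  structure(list(pixels = px, meta = meta, dmap = downsample_map()),
            class = "ecm_dataset")
}

# network with all biases zeroed and batch-norm made an exact identity,
# so the epsilon-rule conservation identity holds exactly at epsilon = 0
zero_bias_network <- function(seed = 5L) {
  m <- build_network(seed)
  for (i in seq_along(m$layers)) {
    l <- m$layers[[i]]
    if (l$type %in% c("conv", "fc")) m$layers[[i]]$b[] <- 0
    if (l$type == "bn") {
      m$layers[[i]]$gamma[] <- 1
      m$layers[[i]]$beta[] <- 0
      m$layers[[i]]$running_mean[] <- 0
      m$layers[[i]]$running_var[] <- 1 - 1e-5   # folded scale exactly 1
    }
  }
  m
}
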