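# shared fixture builders (everything generated in code at test time)

tiny_atlas <- function(grid = c(14L, 14L, 14L)) make_roi_atlas(grid)

tiny_acq <- function(grid = c(14L, 14L, 14L)) acquisition_spec(grid_shape = grid)

# full simulate -> GLM chain for one subject on a small grid
tiny_subject_betas <- function(atlas, effect = effect_spec(), seed = 1L,
                               n_runs = 4, design = "long") {
  acq <- acquisition_spec(grid_shape = atlas$grid_shape)
  sch <- session_schedules(n_runs, design, acq, seed = seed)
  sd1 <- simulate_subject(sch, atlas, effect, seed = seed + 1L)
  subject_betas(sd1, atlas)
}

# direct Gaussian block betas (bypassing the BOLD simulation) for fast
# decode-level tests: condition-mean separation `d` on the first
# `n_informative` voxels
synth_beta_runs <- function(n_runs = 4, reps = 6, nvox = 20, d = 0,
                            n_informative = nvox, seed = 1L,
                            voxels = seq_len(nvox)) {
  set.seed(seed)
  conds <- sound_conditions()
  mu <- matrix(0, 3, nvox)
  if (d > 0 && n_informative > 0) {
    m <- matrix(rnorm(3 * n_informative), 3)
    m <- m - rep(colMeans(m), each = 3)
    mu[, seq_len(n_informative)] <- d * m
  }
  lapply(seq_len(n_runs), function(r) {
    cond <- rep(conds, reps)[sample.int(3 * reps)]
    betas <- matrix(rnorm(length(cond) * nvox), ncol = nvox) +
      mu[match(cond, conds), , drop = FALSE]
    structure(list(betas = betas, condition = cond, run_id = r,
                   voxels = voxels),
              class = "beta_set")
  })
}

# perfectly separable betas (no noise overlap)
separable_beta_runs <- function(n_runs = 4, reps = 2, nvox = 6) {
  conds <- sound_conditions()
  mu <- diag(3) * 10
  lapply(seq_len(n_runs), function(r) {
    cond <- rep(conds, reps)
    set.seed(100 + r)
    betas <- mu[match(cond, conds), rep(1:3, length.out = nvox),
                drop = FALSE] +
      matrix(rnorm(length(cond) * nvox, sd = 0.01), ncol = nvox)
    structure(list(betas = betas, condition = cond, run_id = r,
                   voxels = seq_len(nvox)),
              class = "beta_set")
  })
}
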