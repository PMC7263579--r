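# Fixture builders and a lazy cache for the expensive phantom tables shared
# by the acceptance tests (built once per test run, in code).

# circular annulus slice on an n x n grid with a pixel-value function
# value_fun(r, theta) evaluated at pixel centres; theta measured y-down
make_annulus_slice <- function(n = 64, r_endo = 12, r_epi = 20,
                               value_fun = function(r, th) 1100,
                               center = c((n - 1) / 2, (n - 1) / 2),
                               n_pts = 96, landmark_theta = pi / 2) {
  xg <- matrix(rep(0:(n - 1), each = n), n, n)
  yg <- matrix(rep(0:(n - 1), times = n), n, n)
  rr <- sqrt((xg - center[1])^2 + (yg - center[2])^2)
  th <- atan2(yg - center[2], xg - center[1])
  vals <- matrix(0, n, n)
  myo <- rr >= r_endo & rr <= r_epi
  vals[myo] <- value_fun(rr[myo], th[myo])
  tc <- 2 * pi * (seq_len(n_pts) - 1) / n_pts
  structure(list(
    values = vals, pixel_size = 2.1,
    endo = cbind(x = center[1] + r_endo * cos(tc),
                 y = center[2] + r_endo * sin(tc)),
    epi = cbind(x = center[1] + r_epi * cos(tc),
                y = center[2] + r_epi * sin(tc)),
    landmark = c(x = center[1] + r_epi * cos(landmark_theta),
                 y = center[2] + r_epi * sin(landmark_theta)),
    myo_mask = myo, slice_index = 0L), class = "t1_slice")
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the three-cohort phantom study used by the pipeline-level acceptance tests
phantom_study <- function() {
  cached("study", {
    ds <- generate_dataset(c(control = 50, HCM = 50, DCM = 50), seed = 42)
    X <- extract_dataset(ds)
    base <- baseline_t1(ds)
    list(ds = ds, X = X, global = base$global, segmental = base$segmental)
  })
}

# smaller dataset for the resolution sweep
sweep_study <- function() {
  cached("sweep_ds", generate_dataset(c(control = 20, HCM = 20, DCM = 20),
                                      seed = 99))
}
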