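# Shared fixtures and memoised scenario runs.
#
# Simulations are expensive; scenario trajectories used by several test
# files are computed once per session at reduced resolution and cached.

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(name, ...) {
  key <- paste(name, paste(deparse(list(...)), collapse = ""), sep = "|")
  key <- gsub("[^a-zA-Z0-9_.|=,]", "", key)
  if (!exists(key, .run_cache)) {
    assign(key, run_named_scenario(name, ...), .run_cache)
  }
  get(key, .run_cache)
}

# reduced study resolution used throughout the test suite
test_res <- list(n_circ = 16L, n_axial = 16L)

cached_control <- function() {
  cached_run("control", n_circ = test_res$n_circ, n_axial = test_res$n_axial)
}

# random rigid motion (rotation + translation), seeded by the caller
random_rigid <- function() {
  ang <- stats::runif(3, -pi, pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
              c(0, sin(ang[1]), cos(ang[1])))
  Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0),
              c(-sin(ang[2]), 0, cos(ang[2])))
  Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
              c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  list(R = Rx %*% Ry %*% Rz, t = stats::runif(3, -2, 2))
}

apply_rigid <- function(P, rig) sweep(P %*% t(rig$R), 2, rig$t, "+")
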