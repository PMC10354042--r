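# Shared fixtures, built lazily and cached for the whole test run. The desk
# benchmark (synthetic slides -> library -> trained network) is by far the
# most expensive fixture, so every test that needs a trained network reuses
# the same one.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# trained desk network + library + held-out accuracy (default recipe, seed 1)
get_desk_benchmark <- function() {
  cached("desk_benchmark", run_desk_benchmark(seed = 1))
}

# a small annotated synthetic slide with three planted tumors
get_demo_slide <- function() {
  cached("demo_slide", {
    spec <- slide_layout_spec(
      canvas = c(256, 256),
      tumors = list(
        list(center = c(100, 100), radius = 34,
             composition = c(grade2 = 0.5, grade3 = 0.5)),
        list(center = c(170, 160), radius = 38,
             composition = c(grade3 = 0.6, grade4 = 0.4)),
        list(center = c(90, 185), radius = 22,
             composition = c(grade1 = 1.0))
      ),
      n_airways = 1, seed = 999)
    make_synthetic_slide(spec)
  })
}

# central finite-difference gradient of f at x[i]
num_grad <- function(f, x, i, eps = 1e-6) {
  x1 <- x; x1[i] <- x1[i] + eps
  x2 <- x; x2[i] <- x2[i] - eps
  (f(x1) - f(x2)) / (2 * eps)
}

# hand-rolled grade map: H x W matrix from a run-length description
gm_from_rows <- function(rows, mpp = REFERENCE_MPP) {
  grade_map(do.call(rbind, rows), microns_per_pixel = mpp)
}
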