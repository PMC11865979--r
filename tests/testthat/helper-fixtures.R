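# Shared fixtures, built in code. Heavy corpora are memoized per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

templates <- function() cached("templates", default_templates)

# The study-condition corpus for one analyte: n = 40 over the four default
# concentrations, seed 7 unless stated otherwise.
study_corpus <- function(analyte, seed = 7) {
  cached(sprintf("corpus_%s_%d", analyte, seed), function() {
    generate_training_corpus(templates()[[analyte]], n_per_analyte = 10,
                             seed = seed)
  })
}

# A small, quick corpus for structural tests.
small_corpus <- function(analyte = "dmmp", n = 2, seed = 11,
                         concentrations = c(2.8, 50)) {
  cached(sprintf("small_%s_%d_%d_%d", analyte, n, seed, length(concentrations)),
         function() {
    generate_training_corpus(templates()[[analyte]], n_per_analyte = n,
                             concentrations = concentrations, seed = seed)
  })
}

# A two-Gaussian plasmagram with known ground truth, no noise model involved.
two_peak_plasmagram <- function(a1 = 5, a2 = 3, td1 = 8.7, td2 = 11.2,
                                width = 0.25) {
  dt <- seq(4, 16, by = 0.1)
  plasmagram(dt, a1 * exp(-((dt - td1)^2) / (2 * width^2)) +
                 a2 * exp(-((dt - td2)^2) / (2 * width^2)))
}

random_position <- function() {
  sensor_position(stats::runif(1, -2, 2), stats::runif(1, -2, 2),
                  stats::runif(1, 0, 2))
}
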