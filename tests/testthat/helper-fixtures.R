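# shared fixtures for the suite; everything is generated in code

# a reduced measurement campaign (~200 training vectors) for forest tests
small_layouts <- function() {
  one <- list(
    train = list(c(4L, 4L, 5L), c(4L, 4L, 5L), c(4L, 4L, 4L), c(4L, 4L, 4L)),
    test = list(c(4L, 4L))
  )
  stats::setNames(rep(list(one), 4), tissue_classes())
}

small_config <- function(seed = 11L, ...) {
  dataset_config(layouts = small_layouts(), seed = seed, ...)
}

# memoized default-config dataset (the full 607/62 campaign is used by
# several files; generate it once per test session)
.fixture_cache <- new.env(parent = emptyenv())

default_dataset <- function(seed = 1L) {
  key <- paste0("default_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_dataset(dataset_config(seed = seed))
  }
  .fixture_cache[[key]]
}

# random physical optical parameters for property tests
random_params <- function() {
  d <- runif(1, 0, 0.6)
  cd <- runif(1, -0.5, 0.5)
  if (sqrt(d^2 + cd^2) > 0.95) cd <- cd * 0.5
  optical_params(
    d = d, theta_d = runif(1, 0, pi), cd = cd,
    delta = runif(1, 0, pi), theta_r = runif(1, 0, pi),
    psi = runif(1, -pi / 4, pi / 4),
    a = runif(1, 0.1, 1), b = runif(1, 0.1, 1), c = runif(1, 0.1, 1)
  )
}

# random Stokes vector with DoP <= 1
random_stokes <- function() {
  u <- stats::rnorm(3)
  dop <- runif(1)
  s0 <- runif(1, 0.5, 2)
  c(s0, s0 * dop * u / sqrt(sum(u^2)))
}

# the printed confusion matrix of the trained classifier on the balanced
# test partition (rows = true, cols = predicted; BCC, melanoma, normal, SCC)
published_confusion <- function() {
  matrix(
    c(30, 0, 0, 0,
      0, 30, 0, 0,
      0, 0, 30, 0,
      7, 0, 2, 21),
    nrow = 4, byrow = TRUE,
    dimnames = list(true = tissue_classes(), predicted = tissue_classes())
  )
}

# tiny gaussian 2-feature dataset, linearly separable across `k` classes
toy_gaussian <- function(n_per_class = 20L, k = 3L, sep = 4, sd = 0.5,
                         seed = 1L) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(k), function(cl) {
    cbind(stats::rnorm(n_per_class, cl * sep, sd),
          stats::rnorm(n_per_class, -cl * sep, sd))
  }))
  colnames(x) <- c("f1", "f2")
  list(x = x, y = factor(rep(letters[seq_len(k)], each = n_per_class)))
}
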