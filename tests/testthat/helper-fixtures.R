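# shared fixtures, built once per test run and memoized

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, maker) {
  if (!exists(name, envir = .fixtures)) assign(name, maker(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# interleaved two-moons point set
two_moons <- function(n, noise = 0.15, seed = 1) {
  myodetect:::with_seed(seed, {
    t1 <- runif(n, 0, pi); t2 <- runif(n, 0, pi)
    X <- rbind(cbind(cos(t1), sin(t1)),
               cbind(1 - cos(t2), 0.5 - sin(t2)))
    X + matrix(rnorm(2 * n * 2, 0, noise), 2 * n)
  })
}

# a light detector for pipeline smoke tests (quality not at issue)
tiny_config <- function(...) {
  myo_config(tau = 24, pretrain_maxit = 40L, finetune_epochs = 8L,
             max_pretrain = 400L, max_classifier = 300L, max_regress = 80L,
             ...)
}

tiny_dataset <- function() memo("tiny_dataset", function() {
  make_dataset(8, 2, seed = 42, split = c(train = 6, test = 2))
})

tiny_detector <- function() memo("tiny_detector", function() {
  suppressWarnings(myo_detector(tiny_dataset(), tiny_config(), seed = 5))
})

# the full-scale phantom benchmark detector (fitted once, reused)
bench_dataset <- function() memo("bench_dataset", function() {
  make_dataset(60, 5, seed = 7, split = c(train = 40, test = 20))
})

bench_detector <- function() memo("bench_detector", function() {
  t0 <- proc.time()[3]
  det <- myo_detector(bench_dataset(), myo_config(tau = 24), seed = 1)
  attr(det, "train_elapsed") <- proc.time()[3] - t0
  det
})
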