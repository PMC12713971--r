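# build a band_series whose epoch e has the named feature vector
feature_night <- function(rows, epoch_len = 30) {
  X <- do.call(rbind, rows)
  colnames(X) <- SPECTRAL_STAGES
  as_band_series(X, epoch_len = epoch_len)
}

bg <- c(WAKE = -1, REM = -1, LIGHT = -1, HIDEEP = 0, LODEEP = 0)

test_that("sleep onset is the first long non-Wake run", {
  expect_true(is.na(find_sleep_onset(hypnogram(rep("WAKE", 30)))))
  st <- c("WAKE", "WAKE", rep("LIGHT", 12), "WAKE")
  expect_equal(find_sleep_onset(hypnogram(st), run_len = 10), 2L)
  # brute-force scan oracle on random sequences
  set.seed(6)
  for (i in 1:25) {
    st <- sample(SPECTRAL_STAGES, 60, replace = TRUE,
                 prob = c(0.5, 0.1, 0.2, 0.1, 0.1))
    run_len <- sample(3:12, 1)
    got <- find_sleep_onset(hypnogram(st), run_len)
    want <- NA_integer_
    for (e in seq_len(60 - run_len + 1)) {
      if (all(st[e:(e + run_len - 1)] != "WAKE")) { want <- e - 1L; break }
    }
    expect_identical(got, want)
  }
})

test_that("rule 1 turns deep epochs with beta dominance into REM or Wake", {
  # high beta-to-spindle ratio, spindles below baseline
  rem_like <- c(WAKE = -2, REM = 4, LIGHT = -1, HIDEEP = 5, LODEEP = 2)
  wake_like <- c(WAKE = 6, REM = 4, LIGHT = -1, HIDEEP = 5, LODEEP = 2)
  bands <- feature_night(list(bg, rem_like, wake_like, bg, bg, bg, bg,
                              bg, bg, bg, bg, bg))
  hyp <- hypnogram(c("LIGHT", "HIDEEP", "LODEEP", rep("LIGHT", 9)))
  out <- apply_corrections(hyp, bands)
  expect_equal(out$stages[2], "REM")
  expect_equal(out$stages[3], "WAKE")
  expect_equal(out$changed_from[2:3], c("HIDEEP", "LODEEP"))
})

test_that("rule 2 turns high-total-power low-spindle deep epochs to Wake", {
  noisy <- c(WAKE = 3, REM = 1, LIGHT = -1, HIDEEP = 6, LODEEP = 6)
  rows <- c(list(bg), list(noisy), rep(list(bg), 10))
  bands <- feature_night(rows)
  # total power: epoch 2 is 20 dB above the night median
  bands$total_power <- c(0, 20, rep(0, 10))
  hyp <- hypnogram(c("LIGHT", "HIDEEP", rep("LIGHT", 10)))
  out <- apply_corrections(hyp, bands)
  expect_equal(out$stages[2], "WAKE")
  expect_equal(out$changed_from[2], "HIDEEP")
})

test_that("rule 3 turns spindle-dominant deep epochs into Light", {
  spindly <- c(WAKE = -2, REM = -1, LIGHT = 4, HIDEEP = 2, LODEEP = 1)
  bands <- feature_night(c(list(bg), list(spindly), rep(list(bg), 10)))
  hyp <- hypnogram(c("LIGHT", "HIDEEP", rep("LIGHT", 10)))
  out <- apply_corrections(hyp, bands)
  expect_equal(out$stages[2], "LIGHT")
  expect_equal(out$changed_from[2], "HIDEEP")
})

test_that("rule 4 restores post-onset Wake with sleep rhythms to NREM", {
  deltaish <- c(WAKE = 1, REM = -1, LIGHT = 0, HIDEEP = 5, LODEEP = 2)
  spindlish <- c(WAKE = 1, REM = -1, LIGHT = 4, HIDEEP = 0, LODEEP = 0)
  sleep <- c(WAKE = -2, REM = -1, LIGHT = 3, HIDEEP = 0, LODEEP = 0)
  rows <- c(list(deltaish),            # epoch 1: pre-onset Wake
            rep(list(sleep), 10),      # onset run
            list(deltaish, spindlish), # post-onset Wake epochs
            rep(list(sleep), 2))
  bands <- feature_night(rows)
  hyp <- hypnogram(c("WAKE", rep("LIGHT", 10), "WAKE", "WAKE",
                     rep("LIGHT", 2)))
  out <- apply_corrections(hyp, bands)
  expect_equal(out$stages[1], "WAKE")          # pre-onset gate holds
  expect_true(is.na(out$changed_from[1]))
  expect_equal(out$stages[12], "HIDEEP")       # delta dominant
  expect_equal(out$stages[13], "LIGHT")        # spindles dominant
  expect_equal(out$changed_from[12:13], c("WAKE", "WAKE"))
  expect_equal(out$sleep_onset_epoch, 1L)
})

test_that("an all-Wake night never converts (no onset)", {
  deltaish <- c(WAKE = 1, REM = -1, LIGHT = 0, HIDEEP = 5, LODEEP = 2)
  bands <- feature_night(rep(list(deltaish), 12))
  hyp <- hypnogram(rep("WAKE", 12))
  out <- apply_corrections(hyp, bands)
  expect_equal(out$stages, rep("WAKE", 12))
  expect_true(all(is.na(out$changed_from)))
})

test_that("epochs triggering no rule pass through unchanged", {
  bands <- feature_night(rep(list(bg), 12))
  hyp <- hypnogram(c(rep("LIGHT", 4), "HIDEEP", "LODEEP", "REM",
                     rep("LIGHT", 5)))
  out <- apply_corrections(hyp, bands)
  expect_equal(out$stages, hyp$stages)
  expect_true(all(is.na(out$changed_from)))
})

test_that("corrections are idempotent and markers tally changes", {
  set.seed(17)
  rows <- lapply(1:40, function(i) {
    v <- stats::rnorm(5, c(-1, -1, 0, 1, 1), 2)
    names(v) <- SPECTRAL_STAGES
    v
  })
  bands <- feature_night(rows)
  hyp <- hypnogram(sample(SPECTRAL_STAGES, 40, replace = TRUE,
                          prob = c(0.3, 0.1, 0.2, 0.2, 0.2)))
  once <- apply_corrections(hyp, bands)
  twice <- apply_corrections(once, bands)
  expect_identical(once$stages, twice$stages)
  expect_identical(once$changed_from, twice$changed_from)
  expect_equal(sum(once$stages != hyp$stages),
               sum(!is.na(once$changed_from)))
})

test_that("missing thresholds are reported by name", {
  bands <- feature_night(rep(list(bg), 12))
  hyp <- hypnogram(rep("LIGHT", 12))
  th <- correction_thresholds()
  th$total_db <- NULL
  expect_error(apply_corrections(hyp, bands, th), "total_db")
})

test_that("clean synthetic nights need no corrections", {
  sc <- short_scored()
  expect_lte(sum(!is.na(sc$res$hypnogram$changed_from)), 2)
})
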