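# Tuning grids, stage execution, value selection and cross-corpus consensus.

test_that("default grids match the staged protocol ranges", {
  g <- default_grids()
  expect_length(g$frame_length, 10)
  expect_equal(g$frame_length[1], 20)
  expect_equal(g$frame_length[10], 200)
  expect_equal(diff(g$frame_length), rep(20, 9))
  expect_equal(g$mask_size, 2:12)
  expect_length(g$mod_upper, 11)
  expect_equal(range(g$mod_upper), c(20, 220))
  expect_equal(diff(g$mod_upper), rep(20, 10))
  expect_equal(range(g$acoustic_low), c(0, 1000))
  expect_equal(diff(g$acoustic_low), rep(100, 10))
  expect_equal(range(g$acoustic_high), c(1200, 12000))
  expect_true(all(g$acoustic_range$fa_low < g$acoustic_range$fa_high))
})

test_that("tuned defaults carry the published selected configuration", {
  td <- tuned_defaults()
  expect_equal(td$frame_length_ms, 180)
  expect_equal(td$msh_mask_n, 6L)
  r <- td$ranges
  get <- function(m) unlist(r[r$metric == m, c("fm_high", "fa_low", "fa_high")])
  expect_equal(get("msh"), c(fm_high = 80, fa_low = 200, fa_high = 9000))
  expect_equal(get("cil"), c(fm_high = 80, fa_low = 0, fa_high = 2000))
  expect_equal(get("rala"), c(fm_high = 200, fa_low = 800, fa_high = 6000))
  expect_equal(get("msp25"), c(fm_high = 80, fa_low = 0, fa_high = 1800))
  expect_equal(get("msp75"), c(fm_high = 200, fa_low = 0, fa_high = 2000))
  expect_equal(get("msp95"), c(fm_high = 200, fa_low = 0, fa_high = 9000))
})

test_that("tuned config YAML round-trips", {
  td <- tuned_defaults()
  p <- withr::local_tempfile(fileext = ".yaml")
  write_tuned_config(td, p)
  back <- read_tuned_config(p)
  expect_equal(back$frame_length_ms, td$frame_length_ms)
  expect_equal(back$msh_mask_n, td$msh_mask_n)
  expect_equal(dplyr::arrange(back$ranges, metric),
               dplyr::arrange(td$ranges, metric))
})

test_that("select_best_value honours the tolerance and preference rules", {
  res <- tibble::tibble(value = c(180, 200), mean_efficiency = c(0.899, 0.901))
  expect_equal(select_best_value(res, tolerance = 0.01, prefer = "smallest"), 180)
  # unique maximum wins regardless of preference
  res2 <- tibble::tibble(value = c(20, 40, 60), mean_efficiency = c(0.5, 0.9, 0.6))
  expect_equal(select_best_value(res2, prefer = "smallest"), 40)
  expect_equal(select_best_value(res2, prefer = "largest"), 40)
  # all equal -> preferred extreme of the whole grid
  res3 <- tibble::tibble(value = c(20, 40, 60), mean_efficiency = 0.7)
  expect_equal(select_best_value(res3, prefer = "smallest"), 20)
  expect_equal(select_best_value(res3, prefer = "largest"), 60)
  # permutation invariance of the grid ordering
  perm <- res2[c(3, 1, 2), ]
  expect_equal(select_best_value(perm, prefer = "smallest"),
               select_best_value(res2, prefer = "smallest"))
  expect_error(select_best_value(res2[0, ]), class = "msvoice_error_size")
})

test_that("cross-corpus consensus applies the max-min rule", {
  grid <- c(20, 40, 60)
  a <- tibble::tibble(value = grid, mean_efficiency = c(0.5, 0.8, 0.9))
  b <- tibble::tibble(value = grid, mean_efficiency = c(0.5, 0.9, 0.8))
  # value best in both -> that value
  both <- tibble::tibble(value = grid, mean_efficiency = c(0.5, 0.6, 0.9))
  expect_equal(cross_corpus_consensus(both, both), 60)
  # best only in A, runner-up good in both -> runner-up
  expect_equal(cross_corpus_consensus(a, b), 40)
  expect_error(
    cross_corpus_consensus(a, tibble::tibble(value = c(20, 40),
                                             mean_efficiency = c(0.5, 0.6))),
    class = "msvoice_error_grid")
  # planted common optimum recovered under noise
  withr::with_seed(99, {
    grid <- seq(20, 220, 20)
    bump <- function() 0.5 + 0.3 * exp(-((grid - 120) / 40)^2) + runif(11, 0, 0.03)
    ra <- tibble::tibble(value = grid, mean_efficiency = bump())
    rb <- tibble::tibble(value = grid, mean_efficiency = bump())
    expect_lt(abs(cross_corpus_consensus(ra, rb) - 120), 41)
  })
})

test_that("run_stage evaluates each candidate and is deterministic", {
  co <- small_corpus()
  plan <- small_plan()
  one <- run_stage(co, "rala", "mod_upper", grid = 80, plan = plan)
  expect_equal(nrow(one), 1)
  expect_equal(one$value, 80)
  expect_true(one$mean_efficiency >= 0 && one$mean_efficiency <= 1)

  two <- run_stage(co, "rala", "mod_upper", grid = c(80, 200), plan = plan)
  again <- run_stage(co, "rala", "mod_upper", grid = c(80, 200), plan = plan)
  expect_identical(as.data.frame(two), as.data.frame(again))
  # strong separation holds across the grid on the planted-effect corpus
  expect_true(all(two$mean_efficiency >= 0.9))

  masks <- run_stage(co, "msh", "mask_size", grid = c(2, 6), plan = plan)
  expect_equal(masks$value, c(2, 6))
  expect_error(run_stage(co, "cil", "mask_size", grid = c(2, 6), plan = plan),
               class = "msvoice_error_precondition")

  ac <- run_stage(co, "cil", "acoustic_range",
                  grid = tibble::tibble(fa_low = c(0, 0), fa_high = c(2000, 6000)),
                  plan = plan)
  expect_named(ac, c("fa_low", "fa_high", "mean_efficiency", "sd"))
  sel <- select_best_value(ac, prefer = "smallest")
  expect_s3_class(sel, "tbl_df")
  expect_equal(nrow(sel), 1)
})

test_that("frame-length stage recomputes spectra per candidate", {
  co <- small_corpus()
  plan <- small_plan()
  fl <- run_stage(co, "rala", "frame_length", grid = c(100, 200), plan = plan)
  expect_equal(fl$value, c(100, 200))
  expect_true(all(is.finite(fl$mean_efficiency)))
})

test_that("run_tuning freezes each stage before the next", {
  co <- small_corpus()
  plan <- small_plan()
  grids <- list(frame_length = c(100, 200), mask_size = c(2, 6),
                mod_upper = c(80, 200),
                acoustic_range = tibble::tibble(fa_low = c(0, 800),
                                                fa_high = c(2000, 6000)))
  tr <- run_tuning(co, "rala", plan, grids = grids)
  expect_s3_class(tr$config, "tuned_config")
  expect_named(tr$stages, c("frame_length", "mod_upper", "acoustic_range"))
  # the frozen frame length is the stage-1 selection
  expect_equal(tr$config$frame_length_ms,
               select_best_value(tr$stages$frame_length, prefer = "smallest"))
  r <- tr$config$ranges[tr$config$ranges$metric == "rala", ]
  expect_true(r$fm_high %in% grids$mod_upper)
  # bit-reproducible end to end
  tr2 <- run_tuning(co, "rala", plan, grids = grids)
  expect_identical(as.data.frame(tr$stages$acoustic_range),
                   as.data.frame(tr2$stages$acoustic_range))
  expect_equal(tr$config$ranges, tr2$config$ranges)
})
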