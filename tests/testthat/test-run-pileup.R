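# End-to-end runs over a written .cool fixture, exercising every pile-up
# variant the tool claims: pairs, combinations, two-set crosses, local,
# rescaled, expected / shift / coverage normalization, subsetting, text
# output and the anchored loop-ability table.

fixture_env <- new.env()
get_fixture <- function() {
  if (!is.null(fixture_env$path)) return(fixture_env)
  spec <- synthetic_spec(c(chr1 = 4e6, chr2 = 12e6), 10000, alpha = 1,
                         diagonal_value = 400, bias_sd = 0.2, seed = 88L)
  spec <- plant_loops(spec, tibble(
    chrom = "chr1", bin_i = c(60L, 150L, 260L), bin_j = c(110L, 210L, 320L),
    fold = 4, footprint = 1L))
  spec <- plant_tads(spec, tibble(chrom = "chr2", start_bin = c(200L, 500L),
                                  end_bin = c(260L, 590L), fold = 2))
  dir <- tempfile("fixture"); dir.create(dir)
  path <- file.path(dir, "sim.cool")
  sim <- write_cool_fixture(spec, path, weights = "true")

  bedpe <- file.path(dir, "loops.bedpe")
  writeLines(sprintf("chr1 %d %d chr1 %d %d",
                     c(60, 150, 260) * 10000, c(60, 150, 260) * 10000 + 10000,
                     c(110, 210, 320) * 10000, c(110, 210, 320) * 10000 + 10000),
             bedpe)
  bed <- file.path(dir, "regions.bed")
  writeLines(sprintf("chr%d %d %d r%d", c(1, 1, 1, 2, 2),
                     c(60, 150, 260, 130, 285) * 10000,
                     c(60, 150, 260, 130, 285) * 10000 + 10000, 1:5), bed)
  tads <- file.path(dir, "tads.bed")
  writeLines(sprintf("chr2 %d %d", c(200, 500) * 10000, c(261, 591) * 10000),
             tads)
  fixture_env$path <- path
  fixture_env$bedpe <- bedpe
  fixture_env$bed <- bed
  fixture_env$tads <- tads
  fixture_env$sim <- sim
  fixture_env
}

test_that("every advertised pile-up variant runs on the cool fixture", {
  fx <- get_fixture()
  out <- withr::local_tempfile(fileext = ".txt")

  p_pairs <- suppressMessages(run_pileup(fx$path, fx$bedpe, mode = "pairs",
    flank_bp = 100e3, min_sep = 100e3, seed = 1, out = out))
  expect_equal(dim(p_pairs), c(21L, 21L))
  expect_equal(p_pairs$n_windows, 3L)
  expect_gt(central_enrichment(p_pairs, 1L), 2)  # planted fold-4 loops
  reread <- read_pileup_text(out)
  expect_equal(reread$matrix, p_pairs$matrix)
  expect_equal(reread$n_windows, 3)

  p_comb <- suppressMessages(run_pileup(fx$path, fx$bed, mode = "combinations",
    flank_bp = 50e3, min_sep = 100e3, seed = 1))
  expect_equal(p_comb$n_windows, 4L)  # 3 chr1 pairs + 1 chr2 pair in range

  p_cross <- suppressMessages(run_pileup(fx$path, fx$bed, mode = "cross",
    features2 = fx$bed, flank_bp = 50e3, min_sep = 100e3, seed = 1))
  expect_equal(p_cross$n_windows, p_comb$n_windows)

  p_local <- suppressMessages(run_pileup(fx$path, fx$bed, mode = "local",
    flank_bp = 300e3, normalization = "shifts", n_shifts = 3, seed = 1))
  expect_equal(dim(p_local), c(61L, 61L))

  p_resc <- suppressMessages(run_pileup(fx$path, fx$tads, mode = "rescaled",
    target_size = 33L, normalization = "shifts", n_shifts = 5, seed = 1))
  expect_equal(dim(p_resc), c(33L, 33L))
  # enriched domain interior shows up above the off-domain corners
  inner <- p_resc$matrix[14:20, 14:20]
  corner <- c(p_resc$matrix[1:6, 1:6], p_resc$matrix[28:33, 28:33])
  expect_gt(mean(inner) / mean(corner), 1.3)

  p_cov <- suppressMessages(run_pileup(fx$path, fx$bedpe, mode = "pairs",
    flank_bp = 100e3, balanced = FALSE, coverage = TRUE,
    normalization = "shifts", n_shifts = 3, seed = 1))
  expect_true(isTRUE(p_cov$meta$coverage_normalized))
})

test_that("subsetting beyond the stream size is a no-op; chrom filter applies", {
  fx <- get_fixture()
  p_all <- suppressMessages(run_pileup(fx$path, fx$bedpe, mode = "pairs",
    flank_bp = 100e3, seed = 3))
  p_sub <- suppressMessages(run_pileup(fx$path, fx$bedpe, mode = "pairs",
    flank_bp = 100e3, subset = 100, seed = 3))
  expect_equal(p_sub$matrix, p_all$matrix)

  expect_error(suppressMessages(run_pileup(fx$path, fx$bedpe, mode = "pairs",
    flank_bp = 100e3, chroms = "chr2", seed = 3)),
    class = "hicpileup_no_windows")
})

test_that("fixed seed gives identical results serially and across workers", {
  fx <- get_fixture()
  args <- list(fx$path, fx$bed, mode = "combinations", flank_bp = 60e3,
               min_sep = 100e3, normalization = "shifts", n_shifts = 5)
  p1 <- suppressMessages(do.call(run_pileup, c(args, seed = 7, n_cores = 1)))
  p2 <- suppressMessages(do.call(run_pileup, c(args, seed = 7, n_cores = 1)))
  p4 <- suppressMessages(do.call(run_pileup, c(args, seed = 7, n_cores = 4)))
  expect_identical(p1$matrix, p2$matrix)
  expect_equal(p1$matrix, p4$matrix, tolerance = 1e-12)
  p_other <- suppressMessages(do.call(run_pileup, c(args, seed = 8)))
  expect_false(identical(p1$matrix, p_other$matrix))
})

test_that("heatmap rendering writes an image annotated with the central score", {
  fx <- get_fixture()
  p <- suppressMessages(run_pileup(fx$path, fx$bedpe, mode = "pairs",
    flank_bp = 100e3, seed = 1))
  g <- autoplot(p)
  expect_s3_class(g, "ggplot")
  lab <- vapply(g$layers, function(l) inherits(l$geom, "GeomText"), logical(1))
  expect_true(any(lab))
  ann <- g$layers[[which(lab)[1]]]$aes_params$label
  expect_equal(as.numeric(ann), central_enrichment(p, 1L), tolerance = 1e-3)

  img <- withr::local_tempfile(fileext = ".png")
  plot_pileup(p, img)
  expect_true(file.exists(img) && file.info(img)$size > 0)
})

test_that("the CLI drives pileup, loop-ability, synth and plot, with stdin regions", {
  fx <- get_fixture()
  script <- system.file("cli", "hicpileup.R", package = "hicpileup")
  expect_true(nzchar(script))
  rscript <- file.path(R.home("bin"), "Rscript")
  dir <- withr::local_tempdir()

  out_txt <- file.path(dir, "pileup.txt")
  res <- system2(rscript, c(script, "pileup", "--cool", fx$path,
                            "--features", "-", "--mode", "pairs",
                            "--flank", "100000", "--min-sep", "100000",
                            "--seed", "1", "--out", out_txt),
                 stdin = fx$bedpe, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out_txt))
  p_cli <- read_pileup_text(out_txt)
  p_ref <- suppressMessages(run_pileup(fx$path, fx$bedpe, mode = "pairs",
    flank_bp = 100e3, min_sep = 100e3, seed = 1))
  expect_equal(p_cli$matrix, p_ref$matrix)

  # conflicting normalization flags abort before any compute
  err <- suppressWarnings(system2(rscript, c(script, "pileup", "--cool", fx$path,
                            "--features", fx$bedpe, "--expected", "x.tsv",
                            "--nshifts", "5", "--out", file.path(dir, "y.txt")),
                 stdout = TRUE, stderr = TRUE))
  expect_false(is.null(attr(err, "status")))
  expect_true(any(grepl("mutually exclusive", err)))

  out_tsv <- file.path(dir, "loopability.tsv")
  system2(rscript, c(script, "loopability", "--cool", fx$path,
                     "--features", fx$bed, "--flank", "60000",
                     "--min-sep", "100000", "--seed", "1", "--out", out_tsv),
          stdout = TRUE, stderr = TRUE)
  tab <- utils::read.delim(out_tsv)
  expect_equal(nrow(tab), 5L)
  expect_true(all(c("name", "n_windows", "score", "pass") %in% names(tab)))

  out_cool <- file.path(dir, "synth.cool")
  system2(rscript, c(script, "synth", "--chroms", "2", "--bins", "120",
                     "--resolution", "10000", "--seed", "5",
                     "--out", out_cool), stdout = TRUE, stderr = TRUE)
  x <- read_cool(out_cool)
  expect_equal(n_bins(x$genome, "chr1"), 120L)

  out_png <- file.path(dir, "pileup.png")
  system2(rscript, c(script, "plot", "--in", out_txt, "--out", out_png),
          stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out_png) && file.info(out_png)$size > 0)
})
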