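render_fixture <- function() {
  specs <- tibble::tibble(chrom = c("c1", "c2"), length = c(2000000, 1000000))
  calls <- dplyr::bind_rows(
    make_calls(rep("hom_a", 6), chrom = "c1",
               pos = c(10, 20, 500000, 900000, 1200000, 1900000)),
    make_calls(c("hom_a", "het_ab", "hom_b"), chrom = "c2",
               pos = c(100, 200, 900000))
  )
  list(specs = specs,
       bins = bin_calls(calls, specs, bin_size = 2000000))
}

svg_rects <- function(path) {
  lines <- grep("^<rect", readLines(path), value = TRUE)
  grab <- function(attr) as.numeric(sub(sprintf('.*%s="([0-9.]+)".*', attr),
                                        "\\1", lines))
  tibble::tibble(x = grab("x"), y = grab("y"), w = grab("width"),
                 h = grab("height"),
                 fill = sub('.*fill="([^"]+)".*', "\\1", lines))
}

test_that("identical inputs give byte-identical SVG output", {
  fx <- render_fixture()
  p1 <- tempfile(fileext = ".svg"); p2 <- tempfile(fileext = ".svg")
  render_ideogram(fx$bins, fx$specs, p1)
  render_ideogram(fx$bins, fx$specs, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("chromosome bars scale with physical length", {
  fx <- render_fixture()
  path <- tempfile(fileext = ".svg")
  render_ideogram(fx$bins, fx$specs, path)
  r <- svg_rects(path)
  bars <- r[r$h > 14 | (r$h <= 14 & r$w > 20), ]     # drop legend swatches
  w_c1 <- max(r$w[r$w < 900 & r$w > 100])            # full-length c1 bar
  # c2 (half the bp) must draw at half the pixel width, within 1 px
  widths <- sort(unique(round(r$w[r$w > 100 & r$w < 900])))
  expect_true(any(abs(widths - w_c1 / 2) <= 1))
})

test_that("a pure hom_a sample paints bars only in the parent-A color", {
  specs <- tibble::tibble(chrom = "c1", length = 1000000)
  calls <- make_calls(rep("hom_a", 5), chrom = "c1",
                      pos = c(1, 10, 100, 1000, 999999))
  bins <- bin_calls(calls, specs, bin_size = 1000000)
  path <- tempfile(fileext = ".svg")
  render_ideogram(bins, specs, path)
  r <- svg_rects(path)
  # blue and green appear only as 14px legend swatches, never as bar segments
  expect_true(all(r$w[r$fill %in% c("blue", "green")] == 14))
  expect_true(any(r$fill == "red" & r$w > 100))
})

test_that("hiding a class renormalizes the remaining segments to full height", {
  specs <- tibble::tibble(chrom = "c1", length = 1000)
  calls <- make_calls(c("hom_a", "het_ab"), chrom = "c1", pos = c(10, 20))
  bins <- bin_calls(calls, specs, bin_size = 1000)
  style <- render_style(show_het = FALSE, bar_height = 24)
  path <- tempfile(fileext = ".svg")
  render_ideogram(bins, specs, path, style = style)
  r <- svg_rects(path)
  seg <- r[r$fill == "red" & r$w > 100, ]
  expect_equal(seg$h, 24)           # hom_a alone now fills the whole bar
  expect_false(any(r$fill == "green" & r$w > 14))
})

test_that("bins with no classified sites render in the empty color", {
  specs <- tibble::tibble(chrom = "c1", length = 2000000)
  calls <- make_calls("hom_a", chrom = "c1", pos = 10)
  bins <- bin_calls(calls, specs, bin_size = 1000000)  # second bin empty
  path <- tempfile(fileext = ".svg")
  render_ideogram(bins, specs, path)
  r <- svg_rects(path)
  expect_true(any(r$fill == "lightgray" & r$w > 100))
})

test_that("annotations draw ticks; unknown chromosomes are skipped with warning", {
  fx <- render_fixture()
  ann <- tibble::tibble(chrom = c("c1", "cZ"), start = c(500000, 1),
                        end = c(500000, 1), label = c("Rgene", "ghost"))
  path <- tempfile(fileext = ".svg")
  expect_warning(render_ideogram(fx$bins, fx$specs, path, annotations = ann),
                 "cZ")
  svg <- readLines(path)
  expect_true(any(grepl("<line", svg)))
  expect_true(any(grepl(">Rgene<", svg)))
  expect_false(any(grepl("ghost", svg)))
})

test_that("raster formats write decodable files; unknown formats are fatal", {
  skip_if_not(capabilities("png"))
  fx <- render_fixture()
  png_path <- tempfile(fileext = ".png")
  render_ideogram(fx$bins, fx$specs, png_path, out_format = "png")
  magic <- readBin(png_path, "raw", 8)
  expect_identical(magic[2:4], as.raw(c(0x50, 0x4e, 0x47)))  # "PNG"

  expect_error(render_ideogram(fx$bins, fx$specs, tempfile(), out_format = "tiff"),
               "unknown")
})

test_that("multi-sample bins need an explicit sample choice", {
  fx <- render_fixture()
  bins2 <- dplyr::bind_rows(fx$bins, dplyr::mutate(fx$bins, sample = "s2"))
  expect_error(render_ideogram(bins2, fx$specs, tempfile(fileext = ".svg")),
               "multiple samples")
  p <- tempfile(fileext = ".svg")
  render_ideogram(bins2, fx$specs, p, sample = "s2")
  expect_true(file.size(p) > 0)
  expect_error(render_ideogram(bins2, fx$specs, p, sample = "nope"), "nope")
})

test_that("ggplot helpers return plottable objects", {
  fx <- render_fixture()
  p <- plot_ideogram(fx$bins, fx$specs)
  expect_s3_class(p, "ggplot")
  s <- summarize_contribution(
    make_calls(c("hom_a", "hom_b", "het_ab"))
  )
  expect_s3_class(plot_contribution(s), "ggplot")
})
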