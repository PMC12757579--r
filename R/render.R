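#' Ideogram rendering style
#'
#' Visual parameters for [render_ideogram()]. Defaults follow the field's
#' convention for graphical genotypes: homozygous parent A red, homozygous
#' parent B blue, heterozygous green, bins with no classified sites light
#' gray. Class visibility can be toggled; hidden classes are removed and the
#' remaining segments renormalized to full bar height.
#'
#' @param color_hom_a,color_hom_b,color_het,color_empty Segment colors (R
#'   color names or hex).
#' @param bar_height Chromosome bar height in px.
#' @param spacing Vertical gap between chromosome rows in px.
#' @param font_size Label font size in px.
#' @param canvas_width Total image width in px.
#' @param show_hom_a,show_hom_b,show_het Per-class visibility toggles.
#' @return A `render_style` list, validated.
#' @export
render_style <- function(color_hom_a = "red", color_hom_b = "blue",
                         color_het = "green", color_empty = "lightgray",
                         bar_height = 24, spacing = 18, font_size = 12,
                         canvas_width = 900,
                         show_hom_a = TRUE, show_hom_b = TRUE, show_het = TRUE) {
  cols <- c(color_hom_a, color_hom_b, color_het, color_empty)
  ok <- grepl("^#[0-9A-Fa-f]{6}([0-9A-Fa-f]{2})?$", cols) |
    cols %in% grDevices::colors()
  if (!all(ok)) stop_cp("invalid color(s): ", paste(cols[!ok], collapse = ", "))
  stopifnot(bar_height > 0, spacing >= 0, font_size > 0, canvas_width > 0)
  structure(
    list(color_hom_a = color_hom_a, color_hom_b = color_hom_b,
         color_het = color_het, color_empty = color_empty,
         bar_height = bar_height, spacing = spacing, font_size = font_size,
         canvas_width = canvas_width, show_hom_a = show_hom_a,
         show_hom_b = show_hom_b, show_het = show_het),
    class = "render_style"
  )
}

# Stacked segments for one sample's bins: fixed order hom_a / het_ab / hom_b
# top to bottom, hidden classes dropped and the rest renormalized.
bin_segments <- function(bins, style) {
  stack <- tibble(
    klass = c("hom_a", "het_ab", "hom_b"),
    fill = c(style$color_hom_a, style$color_het, style$color_hom_b),
    shown = c(style$show_hom_a, style$show_het, style$show_hom_b)
  ) |> filter(.data$shown)

  segs <- bins |>
    select("chrom", "start", "end",
           hom_a = "n_hom_a", het_ab = "n_het", hom_b = "n_hom_b") |>
    tidyr::pivot_longer(all_of(c("hom_a", "het_ab", "hom_b")),
                        names_to = "klass", values_to = "n") |>
    filter(.data$klass %in% stack$klass) |>
    mutate(klass = factor(.data$klass, levels = stack$klass)) |>
    arrange(.data$chrom, .data$start, .data$klass) |>
    group_by(.data$chrom, .data$start, .data$end) |>
    mutate(tot = sum(.data$n),
           frac = ifelse(.data$tot > 0, .data$n / .data$tot, 0),
           top = cumsum(dplyr::lag(.data$frac, default = 0)),
           bottom = .data$top + .data$frac) |>
    ungroup() |>
    filter(.data$frac > 0) |>
    left_join(stack[, c("klass", "fill")], by = "klass")

  empties <- bins |>
    mutate(tot = .data$n_hom_a + .data$n_het + .data$n_hom_b) |>
    filter(.data$tot == 0 |
             (.data$tot > 0 & !paste(.data$chrom, .data$start) %in%
                paste(segs$chrom, segs$start))) |>
    mutate(klass = "empty", frac = 1, top = 0, bottom = 1,
           fill = style$color_empty) |>
    select("chrom", "start", "end", "klass", "frac", "top", "bottom", "fill")

  bind_rows(
    segs |> select("chrom", "start", "end", "klass", "frac", "top", "bottom", "fill"),
    empties
  ) |> arrange(.data$chrom, .data$start, .data$top)
}

# Full geometry for one sample: rectangles, lines and text in px, y down.
ideogram_geometry <- function(bins, chrom_specs, annotations = NULL,
                              style = render_style(), title = "") {
  margin_l <- 80; margin_r <- 20; margin_t <- 40
  ann_h <- if (!is.null(annotations) && nrow(annotations) > 0) 16 else 0
  row_h <- style$bar_height + style$spacing + ann_h
  plot_w <- style$canvas_width - margin_l - margin_r
  scale <- plot_w / max(chrom_specs$length)
  legend_h <- style$bar_height + 30
  height <- margin_t + nrow(chrom_specs) * row_h + legend_h

  segs <- bin_segments(bins, style) |>
    mutate(row = match(.data$chrom, chrom_specs$chrom))
  rects <- segs |>
    mutate(
      x = margin_l + (.data$start - 1) * scale,
      w = (.data$end - .data$start + 1) * scale,
      y = margin_t + (.data$row - 1) * row_h + ann_h + .data$top * style$bar_height,
      h = .data$frac * style$bar_height,
      fill = .data$fill
    ) |>
    select("x", "y", "w", "h", "fill")

  texts <- tibble(
    x = c(style$canvas_width / 2, margin_l - 8 + numeric(nrow(chrom_specs))),
    y = c(20, margin_t + (seq_len(nrow(chrom_specs)) - 1) * row_h + ann_h +
            style$bar_height / 2 + style$font_size * 0.35),
    text = c(title, chrom_specs$chrom),
    size = c(style$font_size + 2, rep(style$font_size, nrow(chrom_specs))),
    anchor = c("middle", rep("end", nrow(chrom_specs)))
  )

  lines <- tibble(x1 = numeric(0), y1 = numeric(0),
                  x2 = numeric(0), y2 = numeric(0))
  if (!is.null(annotations) && nrow(annotations) > 0) {
    unknown <- !annotations$chrom %in% chrom_specs$chrom
    if (any(unknown)) {
      warn(paste0("annotation(s) on unknown chromosome skipped: ",
                  paste(unique(annotations$chrom[unknown]), collapse = ", ")))
      annotations <- annotations[!unknown, , drop = FALSE]
    }
    if (nrow(annotations) > 0) {
      row <- match(annotations$chrom, chrom_specs$chrom)
      xm <- margin_l + ((annotations$start + annotations$end) / 2 - 1) * scale
      bar_top <- margin_t + (row - 1) * row_h + ann_h
      lines <- tibble(x1 = xm, y1 = bar_top - 6, x2 = xm, y2 = bar_top)
      texts <- bind_rows(texts, tibble(
        x = xm, y = bar_top - 8, text = annotations$label,
        size = style$font_size - 2, anchor = "middle"
      ))
    }
  }

  # legend: visible classes plus the empty-bin swatch
  leg <- tibble(
    label = c("Hom A", "Het AB", "Hom B", "no data"),
    fill = c(style$color_hom_a, style$color_het, style$color_hom_b,
             style$color_empty),
    shown = c(style$show_hom_a, style$show_het, style$show_hom_b, TRUE)
  ) |> filter(.data$shown)
  ly <- margin_t + nrow(chrom_specs) * row_h + 10
  lx <- margin_l + (seq_len(nrow(leg)) - 1) * 110
  rects <- bind_rows(rects, tibble(x = lx, y = ly, w = 14, h = 14,
                                   fill = leg$fill))
  texts <- bind_rows(texts, tibble(
    x = lx + 18, y = ly + 7 + style$font_size * 0.35, text = leg$label,
    size = style$font_size, anchor = "start"
  ))

  list(width = style$canvas_width, height = height, rects = rects,
       lines = lines, texts = texts, font_size = style$font_size)
}

svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# Deterministic SVG 1.1 emitter: fixed 2-decimal coordinates, no ids, no
# timestamps — identical geometry gives identical bytes.
geometry_to_svg <- function(geo) {
  num <- function(v) sprintf("%.2f", v)
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">',
            num(geo$width), num(geo$height), num(geo$width), num(geo$height)),
    sprintf('<rect x="0" y="0" width="%s" height="%s" fill="white"/>',
            num(geo$width), num(geo$height))
  )
  if (nrow(geo$rects) > 0) {
    out <- c(out, sprintf(
      '<rect x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
      num(geo$rects$x), num(geo$rects$y), num(geo$rects$w), num(geo$rects$h),
      geo$rects$fill
    ))
  }
  if (nrow(geo$lines) > 0) {
    out <- c(out, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black" stroke-width="1"/>',
      num(geo$lines$x1), num(geo$lines$y1), num(geo$lines$x2), num(geo$lines$y2)
    ))
  }
  keep <- nzchar(geo$texts$text)
  if (any(keep)) {
    tx <- geo$texts[keep, ]
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-family="sans-serif" font-size="%s" text-anchor="%s" fill="black">%s</text>',
      num(tx$x), num(tx$y), num(tx$size), tx$anchor, svg_escape(tx$text)
    ))
  }
  c(out, "</svg>")
}

draw_geometry_grid <- function(geo) {
  grid::grid.newpage()
  vp <- grid::viewport(xscale = c(0, geo$width), yscale = c(geo$height, 0))
  grid::pushViewport(vp)
  grid::grid.rect(gp = grid::gpar(fill = "white", col = NA))
  r <- geo$rects
  if (nrow(r) > 0) {
    grid::grid.rect(
      x = grid::unit(r$x, "native"), y = grid::unit(r$y, "native"),
      width = grid::unit(r$w, "native"), height = grid::unit(-r$h, "native"),
      just = c("left", "top"), gp = grid::gpar(fill = r$fill, col = NA)
    )
  }
  l <- geo$lines
  if (nrow(l) > 0) {
    grid::grid.segments(
      x0 = grid::unit(l$x1, "native"), y0 = grid::unit(l$y1, "native"),
      x1 = grid::unit(l$x2, "native"), y1 = grid::unit(l$y2, "native"),
      gp = grid::gpar(col = "black")
    )
  }
  tx <- geo$texts[nzchar(geo$texts$text), ]
  if (nrow(tx) > 0) {
    just <- c(start = 0, middle = 0.5, end = 1)[tx$anchor]
    grid::grid.text(
      tx$text, x = grid::unit(tx$x, "native"), y = grid::unit(tx$y, "native"),
      hjust = just, vjust = 0.8,
      gp = grid::gpar(fontsize = tx$size, fontfamily = "sans")
    )
  }
  grid::popViewport()
}

#' Render a graphical-genotype ideogram
#'
#' Draws one horizontal bar per chromosome, to scale (a shared bp-per-pixel
#' factor across chromosomes), each bin a vertically stacked segment split by
#' its class proportions in fixed order `hom_a` (top), `het_ab`, `hom_b`
#' (bottom). Bins with no classified sites are filled with the empty color so
#' chromosomes render continuously. Annotations draw as ticks with labels
#' above the bar at their scaled midpoint; a legend and the sample title are
#' included. SVG output is deterministic: identical inputs and style give
#' byte-identical files.
#'
#' @param bins Binned calls from [bin_calls()] for a single sample (or pass
#'   `sample` to pick one).
#' @param chrom_specs Chromosome tibble (`chrom`, `length`); sets drawing
#'   order and bar lengths.
#' @param path Output file path.
#' @param annotations Optional annotation tibble ([read_annotations()]);
#'   records on chromosomes not in `chrom_specs` are skipped with a warning.
#' @param style A [render_style()].
#' @param out_format `"svg"`, `"png"` or `"jpeg"`; PNG/JPEG rasterize the
#'   same geometry.
#' @param sample Sample to render when `bins` holds several.
#' @param title Image title; defaults to the sample name.
#' @return `path`, invisibly.
#' @export
render_ideogram <- function(bins, chrom_specs, path, annotations = NULL,
                            style = render_style(),
                            out_format = c("svg", "png", "jpeg"),
                            sample = NULL, title = NULL) {
  if (!is.character(out_format) ||
      !out_format[1] %in% c("svg", "png", "jpeg")) {
    stop_cp("unknown output format: ", out_format[1])
  }
  out_format <- out_format[1]
  samples <- unique(bins$sample)
  if (is.null(sample)) {
    if (length(samples) > 1) {
      stop_cp("bins contain multiple samples; pass `sample` to pick one")
    }
    sample <- samples
  } else if (!sample %in% samples) {
    stop_cp("sample not present in bins: ", sample)
  }
  bins <- bins[bins$sample == sample, , drop = FALSE]
  title <- title %||% as.character(sample)

  geo <- ideogram_geometry(bins, chrom_specs, annotations, style, title)
  if (out_format == "svg") {
    con <- file(path, open = "wb")
    on.exit(close(con), add = TRUE)
    writeLines(geometry_to_svg(geo), con, sep = "\n", useBytes = TRUE)
  } else {
    dev <- if (out_format == "png") grDevices::png else grDevices::jpeg
    dev(path, width = geo$width, height = geo$height, res = 96)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw_geometry_grid(geo)
  }
  invisible(path)
}

#' Quick ggplot of binned graphical genotypes
#'
#' A ggplot2 counterpart of [render_ideogram()] for interactive use: one
#' facet-free panel with chromosomes as rows, bins as stacked proportion
#' segments colored by class. Accepts multi-sample bins (facets by sample).
#'
#' @param bins Tibble from [bin_calls()].
#' @param chrom_specs Chromosome tibble (`chrom`, `length`).
#' @param style A [render_style()] supplying the class colors.
#' @return A ggplot object.
#' @export
plot_ideogram <- function(bins, chrom_specs, style = render_style()) {
  segs <- bins |>
    group_by(.data$sample) |>
    dplyr::group_modify(~bin_segments(.x, style)) |>
    ungroup() |>
    mutate(chrom = factor(.data$chrom, levels = rev(chrom_specs$chrom)))
  fills <- unique(segs$fill)
  p <- ggplot2::ggplot(segs) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start - 1, xmax = .data$end,
      ymin = as.integer(.data$chrom) - 0.35 + 0.7 * .data$top,
      ymax = as.integer(.data$chrom) - 0.35 + 0.7 * .data$bottom,
      fill = .data$fill
    )) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_continuous(breaks = seq_along(levels(segs$chrom)),
                                labels = levels(segs$chrom)) +
    ggplot2::labs(x = "position (bp)", y = NULL) +
    ggplot2::theme_minimal()
  if (length(unique(bins$sample)) > 1) {
    p <- p + ggplot2::facet_wrap(~sample)
  }
  p
}

#' Plot parental contribution percentages
#'
#' Stacked horizontal bars of each sample's genome-wide (or per-chromosome)
#' parental contribution, from a [summarize_contribution()] tibble.
#'
#' @param summary Contribution tibble.
#' @param scope Which scope to plot (default `"genome-wide"`).
#' @param style A [render_style()] supplying the two parental colors.
#' @return A ggplot object.
#' @export
plot_contribution <- function(summary, scope = "genome-wide",
                              style = render_style()) {
  df <- summary |>
    filter(.data$scope == !!scope, !is.na(.data$pct_a)) |>
    select("sample", "pct_a", "pct_b") |>
    tidyr::pivot_longer(c("pct_a", "pct_b"),
                        names_to = "parent", values_to = "pct") |>
    mutate(parent = ifelse(.data$parent == "pct_a", "parent A", "parent B"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pct, y = .data$sample,
                                   fill = .data$parent)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c("parent A" = style$color_hom_a,
                                          "parent B" = style$color_hom_b)) +
    ggplot2::labs(x = "contribution (%)", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
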