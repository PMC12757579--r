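# Shared fixture builders: tiny hand-written VCFs and call tibbles.

write_toy_vcf <- function(body, samples, path = tempfile(fileext = ".vcf"),
                          gz = FALSE) {
  lines <- c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body
  )
  if (gz) {
    con <- gzfile(path)
    writeLines(lines, con)
    close(con)
  } else {
    writeLines(lines, path)
  }
  path
}

vcf_row <- function(chrom, pos, ref, alt, ...) {
  paste(chrom, pos, ".", ref, alt, ".", ".", ".", "GT", ..., sep = "\t")
}

# A call tibble from a vector of class labels at positions 1,2,3,...
make_calls <- function(klasses, chrom = "c1", sample = "s1",
                       pos = seq_along(klasses) * 100) {
  tibble::tibble(chrom = chrom, pos = pos, sample = sample,
                 klass = factor(klasses, levels = klass_levels()))
}

# Exhaustive windowed-majority oracle: materializes every window explicitly.
# Operates on a plain label vector (classified labels only).
oracle_filter_round <- function(x, w) {
  k <- (w - 1) / 2
  n <- length(x)
  out <- x
  for (i in seq_len(n)) {
    left <- if (i > 1) utils::tail(x[seq_len(i - 1)], k) else character(0)
    right <- if (i < n) utils::head(x[seq(i + 1, n)], k) else character(0)
    nb <- c(left, right)
    if (length(nb) == 0) next
    tab <- table(nb)
    maj <- names(tab)[2 * tab > length(nb)]
    if (length(maj) == 1 && maj != x[i]) out[i] <- maj
  }
  out
}

# Run one public filter round on a plain label vector.
filter_labels <- function(x, w = 5, f = 1) {
  out <- sliding_window_filter(make_calls(x), window_size = w, times = f)
  as.character(out$klass)
}
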