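# Fixtures built in code: tiny annotation sets, deterministic coverage
# tracks and small simulations shared across test files.

iso_df <- function(...) {
  rows <- list(...)
  mature_isoforms(do.call(rbind, lapply(rows, function(r)
    data.frame(transcript_id = r[[1]], gene_id = r[[2]], chrom = r[[3]],
               start = as.integer(r[[4]]), end = as.integer(r[[5]]),
               strand = r[[6]], stringsAsFactors = FALSE))))
}

# A constant-coverage track over one chromosome.
flat_track <- function(value = 1, len = 10000, chrom = "chr1",
                       minus_value = value) {
  coverage_track(
    plus = stats::setNames(list(rep(value, len)), chrom),
    minus = stats::setNames(list(rep(minus_value, len)), chrom))
}

# Coverage from explicit vectors.
track_from <- function(plus, minus = NULL, chrom = "chr1") {
  if (is.null(minus)) minus <- numeric(length(plus))
  coverage_track(plus = stats::setNames(list(plus), chrom),
                 minus = stats::setNames(list(minus), chrom))
}

# Small shared simulation (cached per test run).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      arch <- generate_archetypes(15, length_range = c(2000, 25000),
                                  seed = 41)
      tmpl <- synthetic_template_annotations(30, seed = 42)
      cache <<- simulate_dataset(arch, n_genes = 60, templates = tmpl,
                                 seed = 43)
    }
    cache
  }
})
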