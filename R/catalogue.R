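#' Compare two lncRNA catalogues by locus overlap
#'
#' A locus of `a` counts as shared when it overlaps any locus of `b` by at
#' least `min_overlap_bp` base pairs, strand-blind (external catalogues
#' vary in strand reliability).
#'
#' @param a Locus tibble (`chrom`, `start`, `end`, `name`) of the primary
#'   catalogue.
#' @param b Locus tibble of the comparison catalogue.
#' @param min_overlap_bp Minimum overlap in bp to count as shared.
#' @return `a` with an added logical `shared` column; the counts are
#'   `sum(shared)` and `sum(!shared)` (shared + unique = nrow(a)).
#' @export
overlap_catalogues <- function(a, b, min_overlap_bp = 1L) {
  check_intervals(a, "locus")
  check_intervals(b, "locus")
  shared <- vapply(seq_len(nrow(a)), function(i) {
    same <- b$chrom == a$chrom[i]
    any(overlap_bp(a$start[i], a$end[i], b$start[same], b$end[same]) >=
          min_overlap_bp)
  }, logical(1))
  mutate(a, shared = shared)
}

#' Membership of a primary locus set across several catalogues
#'
#' For each locus of the primary set, records whether it overlaps each of
#' the other sets (by [overlap_catalogues()] semantics) and labels the
#' Venn region the locus falls in. Region counts partition the primary
#' set.
#'
#' @param primary Locus tibble of the primary catalogue.
#' @param others Named list of locus tibbles (at least one).
#' @param min_overlap_bp Minimum overlap in bp.
#' @return `primary` with one logical `in_<name>` column per other set and
#'   a `region` column (`"unique"` when in none).
#' @export
multi_set_membership <- function(primary, others, min_overlap_bp = 1L) {
  if (!is.list(others) || length(others) == 0) {
    abort("`others` must be a non-empty list of locus tables")
  }
  if (is.null(names(others)) || any(names(others) == "")) {
    names(others) <- paste0("set", seq_along(others))
  }
  out <- primary
  for (nm in names(others)) {
    out[[paste0("in_", nm)]] <-
      overlap_catalogues(primary, others[[nm]], min_overlap_bp)$shared
  }
  flags <- as.matrix(out[paste0("in_", names(others))])
  region <- apply(flags, 1, function(r) {
    if (!any(r)) "unique" else paste(names(others)[r], collapse = "&")
  })
  mutate(out, region = region)
}

#' Venn region counts of a membership table
#'
#' @param membership Tibble from [multi_set_membership()].
#' @return Tibble with columns `region` and `n`; counts sum to the primary
#'   set size.
#' @export
venn_counts <- function(membership) {
  count(membership, .data$region, name = "n")
}
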