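#' Score marker-phenotype association on a cross panel
#'
#' For every marker, counts the individuals whose genotype class disagrees
#' with the class predicted from their phenotype under the cross design
#' and dominance model. A marker with zero recombinants shows *complete*
#' association with the phenotype, otherwise *incomplete*.
#'
#' Prediction truth tables (A carries the dominant/black allele):
#'
#' * BC1 (F1 x A-line): phenotype 1 predicts `AB`, phenotype 0 predicts
#'   `AA`; any other observed genotype is a recombinant.
#' * F2, A-dominant: phenotype 0 predicts `BB` (a non-`BB` genotype is a
#'   recombinant); phenotype 1 predicts non-`BB` (`BB` is a recombinant).
#'   `AA` vs `AB` are phenotypically identical, so they never count as
#'   recombinant against each other. B-dominant mirrors this.
#'
#' Missing genotypes (`NA` or empty) are excluded per marker, not per
#' individual. Monomorphic markers are uninformative and excluded from
#' the output (their names are kept in the `"uninformative"` attribute).
#'
#' @param panel a [simulate_cross()] panel (or one read back from TSV).
#' @param dominance dominance model; defaults to the panel's own.
#' @return tibble of class `association_records`: `marker`, `pos`,
#'   `recombinant_count`, `n_informative`, `status`.
#' @export
score_association <- function(panel, dominance = NULL) {
  stopifnot(inherits(panel, "cross_panel"))
  if (is.null(dominance)) dominance <- panel$dominance
  if (is.null(dominance)) dominance <- "A-dominant"
  design <- panel$design
  phen <- panel$data$phenotype
  rows <- list()
  uninformative <- character(0)
  for (i in seq_len(nrow(panel$markers))) {
    mk <- panel$markers$marker[[i]]
    g <- panel$data[[mk]]
    ok <- !is.na(g) & g != ""
    gi <- g[ok]; pi <- phen[ok]
    if (length(unique(gi)) < 2) {
      uninformative <- c(uninformative, mk)
      next
    }
    rec <- if (design == "BC1") {
      pred <- ifelse(pi == 1, "AB", "AA")
      sum(gi != pred)
    } else if (dominance == "A-dominant") {
      sum(ifelse(pi == 0, gi != "BB", gi == "BB"))
    } else {
      sum(ifelse(pi == 0, gi != "AA", gi == "AA"))
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      marker = mk, pos = panel$markers$pos[[i]],
      recombinant_count = as.integer(rec),
      n_informative = length(gi),
      status = ifelse(rec == 0, "complete", "incomplete"))
  }
  out <- if (length(rows) == 0)
    tibble::tibble(marker = character(), pos = integer(),
                   recombinant_count = integer(),
                   n_informative = integer(), status = character())
  else dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$pos)
  attr(out, "uninformative") <- uninformative
  structure(out, class = c("association_records", class(out)))
}

#' Delimit the candidate region from association records
#'
#' The candidate interval spans from the last incompletely associated
#' marker left of the (longest) run of completely associated markers to
#' the first incompletely associated marker right of it — the region
#' bounded by "complete association inside, incomplete association at
#' both ends". If no incomplete marker exists on a side, the interval is
#' open to that end of the scaffold (the one-sided case). The procedure
#' is causal-agnostic: it sees only marker statuses.
#'
#' @param records an [score_association()] result (sorted internally by
#'   position).
#' @param scaffold_len scaffold length; used for the open-right endpoint
#'   (defaults to the last marker position + 1).
#' @param features optional tibble `label`, `start`, `end`: features
#'   (e.g. genes) whose overlap with the interval is reported.
#' @return list of class `candidate_interval`: `start`, `end`,
#'   `left_flank_marker`, `right_flank_marker` (NA when open),
#'   `n_complete`, `contains` (feature labels inside the interval).
#' @export
delimit_region <- function(records, scaffold_len = NULL, features = NULL) {
  stopifnot(inherits(records, "association_records"))
  r <- dplyr::arrange(tibble::as_tibble(records), .data$pos)
  comp <- r$status == "complete"
  if (!any(comp)) stop("no completely associated marker: nothing to delimit")
  runs <- rle(comp)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  cruns <- which(runs$values)
  pick <- cruns[which.max(runs$lengths[cruns])]
  i0 <- starts[pick]; i1 <- ends[pick]
  left_open <- i0 == 1
  right_open <- i1 == nrow(r)
  start <- if (left_open) 0 else r$pos[i0 - 1]
  end <- if (right_open) {
    if (is.null(scaffold_len)) r$pos[nrow(r)] + 1 else scaffold_len
  } else r$pos[i1 + 1]
  contains <- character(0)
  if (!is.null(features) && nrow(features) > 0) {
    ov <- features$end > start & features$start < end
    contains <- unique(features$label[ov])
  }
  structure(list(start = start, end = end,
                 left_flank_marker = if (left_open) NA_character_ else
                   r$marker[i0 - 1],
                 right_flank_marker = if (right_open) NA_character_ else
                   r$marker[i1 + 1],
                 n_complete = i1 - i0 + 1L,
                 contains = contains),
            class = "candidate_interval")
}

#' @export
print.candidate_interval <- function(x, ...) {
  cat(sprintf(
    "<candidate_interval> [%s, %s) bounded by %s / %s; %d complete marker(s)%s\n",
    format(x$start, big.mark = ","), format(x$end, big.mark = ","),
    ifelse(is.na(x$left_flank_marker), "scaffold start",
           x$left_flank_marker),
    ifelse(is.na(x$right_flank_marker), "scaffold end",
           x$right_flank_marker),
    x$n_complete,
    if (length(x$contains) > 0)
      paste0("; contains: ", paste(x$contains, collapse = ", ")) else ""))
  invisible(x)
}
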