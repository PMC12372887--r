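#' Default structural region spans (AMPKalpha2 numbering)
#'
#' The four spatial clusters used to localize group-differential residues,
#' expressed as residue ranges in AMPKalpha2 author numbering: the N-lobe,
#' the ATP-pocket ring (hinge plus catalytic loop), the activation loop, and
#' the C-lobe helices. Boundaries are editable; the defaults keep the spans
#' disjoint (the hinge is counted with the ATP pocket, not the N-lobe).
#'
#' @return Named list; each element is a `data.frame` with `start` and `end`
#'   residue numbers (inclusive), possibly several rows per region.
#' @export
default_region_spans <- function() {
  list(
    "N-lobe"          = data.frame(start = 6L,   end = 93L),
    "ATP-pocket"      = data.frame(start = c(94L, 140L), end = c(100L, 150L)),
    "activation-loop" = data.frame(start = 157L, end = 182L),
    "C-lobe-helices"  = data.frame(start = c(101L, 151L, 183L),
                                   end   = c(139L, 156L, 280L))
  )
}

#' Group-differential conservation screen
#'
#' Compares two conservation profiles (inhibited vs non-inhibited kinase
#' group) residue by residue and retains residues whose 1-9 grades differ by
#' at least `min_delta` points. The delta is signed as
#' `grade_inhibited - grade_noninhibited`, so a conservation *decrease* in
#' the non-inhibited group appears as a positive delta; filtering is on
#' `|delta|`. Residues flagged low-confidence in either profile are excluded
#' by default. Residues covered by only one profile are reported in the
#' `"one_sided"` attribute, never silently dropped.
#'
#' @param profile_inhibited,profile_noninhibited Two
#'   [conservation_profile()] results mapped to the same reference numbering.
#' @param min_delta Minimum absolute grade difference to retain (default 3).
#' @param omit_low_confidence Drop residues flagged in either profile
#'   (default `TRUE`).
#' @return `data.frame` with `residue_number`, `grade_inhibited`,
#'   `grade_noninhibited`, `delta`, `either_low_confidence`, `region`
#'   (initially `"unassigned"`), sorted by residue number. Attribute
#'   `one_sided` lists residues present in only one profile.
#' @export
grade_delta <- function(profile_inhibited, profile_noninhibited,
                        min_delta = 3, omit_low_confidence = TRUE) {
  stopifnot(min_delta >= 1)
  pi_ <- profile_inhibited[!is.na(profile_inhibited$residue_number), ]
  pn <- profile_noninhibited[!is.na(profile_noninhibited$residue_number), ]
  if (nrow(pi_) == 0 || nrow(pn) == 0) {
    stop("profiles must be mapped to reference residue numbers")
  }
  shared <- intersect(pi_$residue_number, pn$residue_number)
  one_sided <- sort(c(setdiff(pi_$residue_number, pn$residue_number),
                      setdiff(pn$residue_number, pi_$residue_number)))
  if (length(shared) == 0) {
    warning("the two profiles cover disjoint residue sets")
  }
  ii <- match(shared, pi_$residue_number)
  ni <- match(shared, pn$residue_number)
  out <- data.frame(
    residue_number = shared,
    grade_inhibited = pi_$grade[ii],
    grade_noninhibited = pn$grade[ni],
    delta = pi_$grade[ii] - pn$grade[ni],
    either_low_confidence = pi_$low_confidence[ii] | pn$low_confidence[ni],
    region = rep("unassigned", length(shared)), stringsAsFactors = FALSE)
  keep <- abs(out$delta) >= min_delta
  if (omit_low_confidence) keep <- keep & !out$either_low_confidence
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$residue_number), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "one_sided") <- one_sided
  out
}

#' Assign differential residues to structural regions
#'
#' Each residue is assigned to the region whose span contains it; residues
#' outside every span stay `"unassigned"`. Spans must be pairwise disjoint.
#'
#' @param deltas Output of [grade_delta()].
#' @param region_spans Named list of span tables as in
#'   [default_region_spans()].
#' @return `deltas` with the `region` column filled.
#' @export
assign_regions <- function(deltas, region_spans = default_region_spans()) {
  spans <- do.call(rbind, lapply(names(region_spans), function(nm) {
    s <- region_spans[[nm]]
    data.frame(region = nm, start = s$start, end = s$end,
               stringsAsFactors = FALSE)
  }))
  if (any(spans$start > spans$end)) stop("region span with start > end")
  covered <- unlist(Map(seq, spans$start, spans$end))
  if (anyDuplicated(covered)) {
    stop("region spans overlap at residue(s) ",
         paste(utils::head(sort(unique(covered[duplicated(covered)])), 5),
               collapse = ", "))
  }
  deltas$region <- vapply(deltas$residue_number, function(r) {
    hit <- spans$region[r >= spans$start & r <= spans$end]
    if (length(hit) == 0) "unassigned" else hit[1]
  }, character(1))
  deltas
}

#' Write a differential-conservation table as TSV
#'
#' @param deltas Output of [grade_delta()] / [assign_regions()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_deltas <- function(deltas, file) {
  utils::write.table(as.data.frame(deltas), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}
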