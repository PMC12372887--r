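#' Read a kinome-panel remaining-activity table
#'
#' Parses a CSV/TSV table of per-kinase remaining activity measurements into
#' a validated panel record table. Column names are configurable so tables
#' exported from different screening services can be read without editing.
#' When a table carries duplicate measurements per (kinase, compound) they are
#' averaged and the SEM across duplicates is retained for reporting.
#'
#' @param file Path to a delimited text file with a header row.
#' @param kinase_col,compound_col,activity_col Names of the columns holding
#'   the kinase identifier, compound identifier and percent remaining
#'   activity.
#' @param sem_col Optional name of a column with the SEM of the activity.
#' @param sep Field separator; `","` (default) or `"\t"`.
#' @return A `data.frame` of class `panel_table` with columns `kinase_id`,
#'   `compound_id`, `remaining_activity`, `sem`, `n_replicates`. Kinase ids
#'   are whitespace-stripped; comparisons elsewhere are case-insensitive.
#' @export
read_panel_table <- function(file, kinase_col = "kinase_id",
                             compound_col = "compound_id",
                             activity_col = "remaining_activity",
                             sem_col = NULL, sep = ",") {
  if (!file.exists(file)) stop("panel table not found: ", file)
  raw <- utils::read.table(file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"")
  needed <- c(kinase_col, compound_col, activity_col)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("panel table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0) {
    return(empty_panel_table())
  }
  act <- suppressWarnings(as.numeric(raw[[activity_col]]))
  bad <- which(is.na(act) | !is.finite(act) | act < 0)
  if (length(bad) > 0) {
    # +1 for the header line so reported numbers match the file
    stop("non-numeric or negative remaining_activity at line(s) ",
         paste(bad + 1L, collapse = ", "), " (values: ",
         paste(raw[[activity_col]][bad], collapse = ", "), ")")
  }
  kin <- trimws(as.character(raw[[kinase_col]]))
  if (any(!nzchar(kin))) {
    stop("empty kinase_id at line(s) ",
         paste(which(!nzchar(kin)) + 1L, collapse = ", "))
  }
  cmp <- trimws(as.character(raw[[compound_col]]))
  sem <- if (!is.null(sem_col) && sem_col %in% names(raw)) {
    suppressWarnings(as.numeric(raw[[sem_col]]))
  } else {
    rep(NA_real_, nrow(raw))
  }
  tab <- data.frame(kinase_id = kin, compound_id = cmp,
                    remaining_activity = act, sem = sem,
                    n_replicates = 1L, stringsAsFactors = FALSE)
  tab <- aggregate_panel_replicates(tab)
  class(tab) <- c("panel_table", "data.frame")
  tab
}

empty_panel_table <- function() {
  tab <- data.frame(kinase_id = character(0), compound_id = character(0),
                    remaining_activity = numeric(0), sem = numeric(0),
                    n_replicates = integer(0), stringsAsFactors = FALSE)
  class(tab) <- c("panel_table", "data.frame")
  tab
}

# Collapse duplicate (kinase, compound) rows to their mean; SEM across the
# duplicates replaces any per-row SEM (classification uses means).
aggregate_panel_replicates <- function(tab) {
  key <- paste(tolower(tab$kinase_id), tab$compound_id, sep = "\r")
  if (!anyDuplicated(key)) return(tab)
  idx <- split(seq_len(nrow(tab)), key)
  rows <- lapply(idx, function(i) {
    a <- tab$remaining_activity[i]
    data.frame(kinase_id = tab$kinase_id[i[1]],
               compound_id = tab$compound_id[i[1]],
               remaining_activity = mean(a),
               sem = if (length(a) > 1) stats::sd(a) / sqrt(length(a))
                     else tab$sem[i[1]],
               n_replicates = length(a), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(tolower(out$kinase_id), tolower(tab$kinase_id))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a panel table to CSV
#'
#' @param tab A `panel_table`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_panel_table <- function(tab, file) {
  utils::write.csv(as.data.frame(tab), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Partition panel kinases into inhibited / non-inhibited groups
#'
#' Applies the two remaining-activity thresholds used to define compound
#' selectivity groups: a kinase is *inhibited* when its remaining activity is
#' at or below `inhibited_cutoff` (default 50%), *non-inhibited* when at or
#' above `noninhibited_cutoff` (default 99%), and *unclassified* in between.
#' Both boundaries are inclusive. The unclassified band is kept as an explicit
#' third set so reports can show how many kinases fall between the cutoffs.
#'
#' @param tab A `panel_table`.
#' @param compound_id Compound to classify on.
#' @param inhibited_cutoff,noninhibited_cutoff Percent remaining-activity
#'   cutoffs; must satisfy `inhibited_cutoff < noninhibited_cutoff`.
#' @return An object of class `selectivity_groups`: a list with character
#'   vectors `inhibited`, `noninhibited`, `unclassified` plus the cutoffs and
#'   compound id used.
#' @export
classify_groups <- function(tab, compound_id, inhibited_cutoff = 50,
                            noninhibited_cutoff = 99) {
  stopifnot(is.numeric(inhibited_cutoff), is.numeric(noninhibited_cutoff))
  if (!(inhibited_cutoff < noninhibited_cutoff)) {
    stop("inhibited_cutoff must be strictly below noninhibited_cutoff")
  }
  sub <- tab[tab$compound_id == compound_id, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop("no panel records for compound '", compound_id, "'")
  }
  a <- sub$remaining_activity
  groups <- list(
    inhibited    = sub$kinase_id[a <= inhibited_cutoff],
    noninhibited = sub$kinase_id[a >= noninhibited_cutoff],
    unclassified = sub$kinase_id[a > inhibited_cutoff &
                                 a < noninhibited_cutoff],
    inhibited_cutoff = inhibited_cutoff,
    noninhibited_cutoff = noninhibited_cutoff,
    compound_id = compound_id
  )
  class(groups) <- "selectivity_groups"
  groups
}

#' @export
print.selectivity_groups <- function(x, ...) {
  cat(sprintf(
    "Selectivity groups for %s (<=%g%% inhibited, >=%g%% non-inhibited)\n",
    x$compound_id, x$inhibited_cutoff, x$noninhibited_cutoff))
  cat(sprintf("  inhibited:    %d\n  noninhibited: %d\n  unclassified: %d\n",
              length(x$inhibited), length(x$noninhibited),
              length(x$unclassified)))
  invisible(x)
}

#' Overlap of the inhibited sets of two compounds
#'
#' Computes the Venn partition of two compounds' inhibited kinase sets:
#' kinases inhibited only by the first compound, only by the second, and by
#' both. Identifiers are compared case-insensitively.
#'
#' @param groups_a,groups_b Two `selectivity_groups` objects.
#' @return A list with character vectors `only_a`, `only_b`, `both`, integer
#'   `counts`, and the two compound ids.
#' @export
overlap_groups <- function(groups_a, groups_b) {
  stopifnot(inherits(groups_a, "selectivity_groups"),
            inherits(groups_b, "selectivity_groups"))
  universe_a <- tolower(c(groups_a$inhibited, groups_a$noninhibited,
                          groups_a$unclassified))
  universe_b <- tolower(c(groups_b$inhibited, groups_b$noninhibited,
                          groups_b$unclassified))
  if (!setequal(universe_a, universe_b)) {
    warning("the two groups were derived from different kinase universes")
  }
  a <- groups_a$inhibited
  b <- groups_b$inhibited
  al <- tolower(a); bl <- tolower(b)
  out <- list(only_a = a[!(al %in% bl)],
              only_b = b[!(bl %in% al)],
              both   = a[al %in% bl],
              compound_a = groups_a$compound_id,
              compound_b = groups_b$compound_id)
  out$counts <- c(only_a = length(out$only_a), only_b = length(out$only_b),
                  both = length(out$both))
  out
}

#' Serialize selectivity groups to JSON
#'
#' @param groups A `selectivity_groups` object.
#' @param file Optional path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `file`).
#' @export
groups_to_json <- function(groups, file = NULL) {
  x <- unclass(groups)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}
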