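# Machine-readable transcriptions of the published comparison tables and
# the routine that re-derives the printed variance-percentage table from
# the observer table.

FIXTURE_CHECKSUMS <- c(
  table2_observers.csv = "7c2b87cab0e5bdab00bf368468d17e07",
  table3_printed.csv   = "2016a815d83ce21c46e9bfd745b7e84e",
  table1_matches.csv   = "951f6651aa066b7ccfac17f728010133"
)

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "sonocyst")
  if (p == "") stop(sprintf("fixture `%s` not found in the installed package", file),
                    call. = FALSE)
  p
}

#' Load the packaged published-table fixtures
#'
#' Returns the transcription of the published comparison tables: the
#' 26-nodule x 4-observer cystic-percentage table (`table2`), the printed
#' per-physician variance-percentage table including its NA cells
#' (`table3_printed`), and the four printed classification match
#' percentages (`table1_printed`). File checksums are verified on load.
#'
#' @return A list of class `fixture_bundle`.
#' @export
load_fixtures <- function() {
  for (f in names(FIXTURE_CHECKSUMS)) {
    sum <- unname(tools::md5sum(fixture_path(f)))
    if (!identical(sum, unname(FIXTURE_CHECKSUMS[f]))) {
      stop(sprintf("fixture `%s` failed its integrity checksum", f), call. = FALSE)
    }
  }
  table2 <- observer_table(utils::read.csv(fixture_path("table2_observers.csv")))
  table3 <- utils::read.csv(fixture_path("table3_printed.csv"))
  table1 <- utils::read.csv(fixture_path("table1_matches.csv"),
                            check.names = FALSE)
  stopifnot(nrow(table2) == 26L, nrow(table3) == 26L, nrow(table1) == 4L)
  structure(list(table2 = table2,
                 table3_printed = table3,
                 table1_printed = table1),
            class = "fixture_bundle")
}

#' Re-derive the printed variance-percentage table from the observer table
#'
#' Recomputes every per-physician variance percentage from the packaged
#' observer table and compares cell by cell against the printed table:
#' numeric cells must agree within `tolerance` (default 0.1, absorbing the
#' printed truncation), NA cells must be NA in both. Cells where both
#' observers report 0 follow the package's 0/0 -> 0 convention; printed
#' cells that disagree with that convention are listed under
#' `discrepant_cells` rather than counted as mismatches of the formula.
#'
#' @param bundle A [load_fixtures()] bundle.
#' @param tolerance Absolute tolerance for numeric cells.
#' @return A list with `computed` (raw variance table), `cell_diffs`
#'   (long data.frame with per-cell status), `n_matching`,
#'   `discrepant_cells` and `mismatched_cells`.
#' @export
reproduce_table3 <- function(bundle = load_fixtures(), tolerance = 0.1) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  computed <- variance_table(bundle$table2, reference_column = "DSS")
  phys <- setdiff(names(computed), "nodule_id")
  rows <- list()
  for (p in phys) {
    comp <- computed[[p]]
    prt <- bundle$table3_printed[[p]]
    obs1 <- bundle$table2[[p]]
    obs2 <- bundle$table2[["DSS"]]
    status <- character(length(comp))
    for (i in seq_along(comp)) {
      status[i] <- if (is.na(comp[i]) && is.na(prt[i])) {
        "na_match"
      } else if (!is.na(comp[i]) && !is.na(prt[i]) &&
                 abs(comp[i] - prt[i]) <= tolerance) {
        "match"
      } else if (obs1[i] == 0 && obs2[i] == 0) {
        "zero_convention_discrepant"
      } else {
        "mismatch"
      }
    }
    rows[[p]] <- data.frame(nodule_id = computed$nodule_id, physician = p,
                            observer1 = obs1, reference = obs2,
                            computed = comp, printed = prt, status = status)
  }
  cell_diffs <- do.call(rbind, rows)
  rownames(cell_diffs) <- NULL
  list(computed = computed,
       cell_diffs = cell_diffs,
       n_matching = sum(cell_diffs$status %in% c("match", "na_match")),
       discrepant_cells = cell_diffs[cell_diffs$status == "zero_convention_discrepant", ],
       mismatched_cells = cell_diffs[cell_diffs$status == "mismatch", ])
}
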