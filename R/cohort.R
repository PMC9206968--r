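#' NIH Stroke Scale item catalog
#'
#' The 15 NIHSS item subscores used throughout the package, with their
#' maximum scores. Higher scores indicate greater deficit severity. Items
#' whose maxima vary across NIHSS revisions use the trial-era instrument
#' (sensory 0-2).
#'
#' @return A data frame with columns `item` (short variable name),
#'   `display_name` (symptom description) and `max_score` (integer maximum
#'   of the ordinal scale; the minimum is always 0).
#' @examples
#' cat <- nihss_catalog()
#' nrow(cat) # 15 items
#' @export
nihss_catalog <- function() {
  data.frame(
    item = c(
      "ATAXIA", "CONSCIO", "DYSAR", "EXTIN", "GAZE", "LANG", "LOCCOM",
      "LOCQU", "MOTORLA", "MOTORLL", "MOTORRA", "MOTORRL", "PALSY",
      "SENSORY", "VISUAL"
    ),
    display_name = c(
      "Coordination", "Level of consciousness", "Speech (slurring)",
      "Spatial perception", "Eye movements", "Language",
      "Command following", "Question answering", "Left arm strength",
      "Left leg strength", "Right arm strength", "Right leg strength",
      "Facial weakness", "Skin sensation (pain/pinprick)", "Visual fields"
    ),
    max_score = c(2L, 3L, 2L, 2L, 2L, 3L, 2L, 2L, 4L, 4L, 4L, 4L, 3L,
                  2L, 3L),
    stringsAsFactors = FALSE
  )
}

# order patient ids numerically when they all look numeric, else lexically
order_patient_ids <- function(ids) {
  num <- suppressWarnings(as.numeric(ids))
  if (!anyNA(num)) ids[order(num)] else sort(ids, method = "radix")
}

validate_item_catalog <- function(items) {
  if (!is.data.frame(items) || !all(c("item", "max_score") %in% names(items)))
    stop("item catalog must be a data frame with columns 'item' and 'max_score'")
  if (is.null(items$display_name)) items$display_name <- items$item
  items$item <- as.character(items$item)
  if (anyDuplicated(items$item))
    stop("duplicated item id in catalog: ", items$item[duplicated(items$item)][1])
  ms <- items$max_score
  if (any(is.na(ms)) || any(ms != as.integer(ms)) || any(ms < 1))
    stop("max_score must be a positive integer for every item")
  items$max_score <- as.integer(ms)
  items[, c("item", "display_name", "max_score")]
}

#' Construct a longitudinal cohort tensor
#'
#' Bundles an integer score array `X[patient, item, timepoint]` with its
#' item catalog and optional treatment-arm labels, validating score bounds
#' (`0 <= X <= max_score(item)`), completeness and integrality. Patients are
#' stored in a canonical ascending order; timepoints are the ranks
#' `0..M-1`.
#'
#' @param scores integer array `[N, V, M]`; dimnames give patient ids, item
#'   ids and timepoint labels (timepoints are remapped to ranks `0..M-1`).
#' @param items item catalog (`item`, `display_name`, `max_score`), e.g.
#'   [nihss_catalog()]; row order defines the item axis.
#' @param arm optional per-patient treatment label, `"treated"` or
#'   `"placebo"`, named by patient id.
#' @return An object of class `cohort_tensor`: a list with `scores`,
#'   `items`, `patients`, `timepoints` and `arm`.
#' @export
cohort_tensor <- function(scores, items, arm = NULL) {
  items <- validate_item_catalog(items)
  if (length(dim(scores)) != 3L)
    stop("scores must be a 3-d array [patient, item, timepoint]")
  n <- dim(scores)[1]; v <- dim(scores)[2]; m <- dim(scores)[3]
  if (n < 2L) stop("cohort must contain at least 2 patients")
  if (v < 1L || v != nrow(items))
    stop("item axis length (", v, ") must match the catalog (", nrow(items), ")")
  if (m < 2L) stop("cohort must contain at least 2 timepoints")
  pats <- dimnames(scores)[[1]]
  if (is.null(pats)) pats <- as.character(seq_len(n))
  if (anyDuplicated(pats)) stop("duplicated patient id: ",
                                pats[duplicated(pats)][1])
  if (anyNA(scores)) stop("scores must not contain missing values")
  if (any(scores != round(scores)))
    stop("scores must be integers (ordinal levels); refusing to coerce")
  storage.mode(scores) <- "integer"
  maxes <- items$max_score
  for (j in seq_len(v)) {
    sj <- scores[, j, , drop = FALSE]
    if (any(sj < 0L) || any(sj > maxes[j]))
      stop("score out of range for item '", items$item[j], "': allowed 0..",
           maxes[j], ", found ", paste(range(sj), collapse = ".."))
  }
  ord <- match(order_patient_ids(pats), pats)
  scores <- scores[ord, , , drop = FALSE]
  pats <- pats[ord]
  dimnames(scores) <- list(pats, items$item, as.character(seq_len(m) - 1L))
  if (!is.null(arm)) {
    if (is.null(names(arm))) {
      if (length(arm) != n) stop("arm labels must be named or length N")
      names(arm) <- dimnames(scores)[[1]]
    }
    arm <- as.character(arm[pats])
    if (anyNA(arm) || !all(arm %in% c("treated", "placebo")))
      stop("arm must assign 'treated' or 'placebo' to every patient")
    names(arm) <- pats
  }
  structure(
    list(scores = scores, items = items, patients = pats,
         timepoints = seq_len(m) - 1L, arm = arm),
    class = "cohort_tensor"
  )
}

#' @export
print.cohort_tensor <- function(x, ...) {
  cat("cohort_tensor:", length(x$patients), "patients x", nrow(x$items),
      "items x", length(x$timepoints), "timepoints\n")
  if (!is.null(x$arm))
    cat("  arm: ", sum(x$arm == "treated"), " treated / ",
        sum(x$arm == "placebo"), " placebo\n", sep = "")
  invisible(x)
}

#' @export
dim.cohort_tensor <- function(x) dim(x$scores)

#' Load a cohort from long-format CSV files
#'
#' Reads a long score table (`patient,item,timepoint,score[,arm]`) and an
#' item-metadata table (`item[,display_name],max_score`) and assembles a
#' dense, validated [cohort_tensor()]. Every (patient, item, timepoint)
#' triple must appear exactly once; timepoint labels are sorted ascending
#' and mapped to ranks `0..M-1`; patients are sorted ascending; items keep
#' the metadata-file order.
#'
#' @param scores_path path to the long-format score CSV.
#' @param meta_path path to the item-metadata CSV.
#' @return A [cohort_tensor()].
#' @export
load_cohort <- function(scores_path, meta_path) {
  for (p in c(scores_path, meta_path))
    if (!file.exists(p)) stop("cohort file not found: ", p)
  items <- validate_item_catalog(
    utils::read.csv(meta_path, stringsAsFactors = FALSE))
  tab <- utils::read.csv(scores_path, stringsAsFactors = FALSE)
  need <- c("patient", "item", "timepoint", "score")
  if (!all(need %in% names(tab)))
    stop("score table must have columns ", paste(need, collapse = ", "))
  tab$patient <- as.character(tab$patient)
  tab$item <- as.character(tab$item)
  if (!all(tab$item %in% items$item))
    stop("unknown item in score table: ", setdiff(tab$item, items$item)[1])
  if (any(is.na(tab$timepoint)) || !is.numeric(tab$timepoint))
    stop("timepoint must be numeric")

  pats <- order_patient_ids(unique(tab$patient))
  tps <- sort(unique(tab$timepoint))
  key <- paste(tab$patient, tab$item, tab$timepoint, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    d <- tab[dup, ][1, ]
    stop("duplicated observation for (patient=", d$patient, ", item=",
         d$item, ", timepoint=", d$timepoint, ")")
  }
  full <- expand.grid(timepoint = tps, item = items$item, patient = pats,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fkey <- paste(full$patient, full$item, full$timepoint, sep = "\r")
  hit <- match(fkey, key)
  if (anyNA(hit)) {
    miss <- full[which(is.na(hit))[1], ]
    stop("incomplete cohort: missing observation for (patient=",
         miss$patient, ", item=", miss$item, ", timepoint=",
         miss$timepoint, ")")
  }
  sc <- tab$score[hit]
  if (anyNA(sc) || any(sc != round(sc)))
    stop("scores must be integers (ordinal levels); refusing to coerce")
  arr <- array(as.integer(sc),
               dim = c(length(tps), nrow(items), length(pats)),
               dimnames = list(as.character(tps), items$item, pats))
  arr <- aperm(arr, c(3, 2, 1))
  arm <- NULL
  if ("arm" %in% names(tab)) {
    ptab <- unique(tab[, c("patient", "arm")])
    if (anyDuplicated(ptab$patient))
      stop("inconsistent arm label for patient ",
           ptab$patient[duplicated(ptab$patient)][1])
    arm <- stats::setNames(as.character(ptab$arm), ptab$patient)
  }
  cohort_tensor(arr, items, arm = arm)
}

#' Write a cohort to a long-format CSV file
#'
#' Inverse of [load_cohort()]: `load_cohort(write_cohort(c, ...), ...)`
#' reproduces `c` exactly (scores, ordering, arm labels).
#'
#' @param cohort a [cohort_tensor()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_tensor"))
  x <- cohort$scores
  df <- data.frame(
    patient = rep(cohort$patients, each = nrow(cohort$items) *
                    length(cohort$timepoints)),
    item = rep(rep(cohort$items$item, each = length(cohort$timepoints)),
               times = length(cohort$patients)),
    timepoint = rep(cohort$timepoints,
                    times = length(cohort$patients) * nrow(cohort$items)),
    stringsAsFactors = FALSE
  )
  df$score <- x[cbind(match(df$patient, cohort$patients),
                      match(df$item, cohort$items$item),
                      df$timepoint + 1L)]
  if (!is.null(cohort$arm)) df$arm <- unname(cohort$arm[df$patient])
  ok <- tryCatch(
    {utils::write.csv(df, path, row.names = FALSE, quote = FALSE); TRUE},
    error = function(e) stop("cannot write cohort file '", path, "': ",
                             conditionMessage(e))
  )
  invisible(path)
}

#' Write an item catalog to CSV
#'
#' @param items an item catalog data frame as in [nihss_catalog()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(items, path) {
  items <- validate_item_catalog(items)
  utils::write.csv(items, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
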