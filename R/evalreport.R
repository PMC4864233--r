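capri_categories <- c("High", "Medium", "Acceptable", "Incorrect")

check_records <- function(records) {
  stopifnot(is.data.frame(records), "id" %in% names(records))
  if (anyDuplicated(records$id)) stop("duplicate ids in quality records")
  records
}

#' Category composition of a selection
#'
#' @param selection Character vector of selected decoy ids (non-empty).
#' @param records data.frame of quality records with columns `id` and
#'   `category` (and `fnat`, `fnonnat` for [recall_precision()]).
#' @return Named numeric vector: fraction of the selection in each CAPRI
#'   category (sums to 1).
#' @export
enrichment <- function(selection, records) {
  check_records(records)
  if (length(selection) == 0) stop("empty selection")
  i <- match(selection, records$id)
  if (anyNA(i)) stop("missing quality record for: ",
                     paste(selection[is.na(i)], collapse = ", "))
  cat_f <- factor(records$category[i], levels = capri_categories)
  tab <- table(cat_f)
  stats::setNames(as.numeric(tab) / length(selection), names(tab))
}

#' Mean Recall and Precision of a selection
#'
#' Recall is the mean fraction of native contacts (fnat); Precision is the
#' mean 1 - fnonnat. Decoys without contacts contribute fnat = 0 and
#' Precision 1.
#'
#' @inheritParams enrichment
#' @return Named numeric vector `c(recall = ..., precision = ...)`.
#' @export
recall_precision <- function(selection, records) {
  check_records(records)
  if (length(selection) == 0) stop("empty selection")
  i <- match(selection, records$id)
  if (anyNA(i)) stop("missing quality record for: ",
                     paste(selection[is.na(i)], collapse = ", "))
  c(recall = mean(records$fnat[i]), precision = mean(1 - records$fnonnat[i]))
}

#' Plot-ready table of binding free energy against interface RMSD
#'
#' @param records Quality records data.frame with `id` and `irms_A`.
#' @param scores Named numeric vector of binding free energies (kJ/mol),
#'   names aligned with `records$id`.
#' @return data.frame with `id`, `irms_A`, `dg_off`, sorted by id.
#' @export
scatter_table <- function(records, scores) {
  check_records(records)
  if (is.null(names(scores))) stop("scores must be named by decoy id")
  miss <- setdiff(records$id, names(scores))
  if (length(miss) > 0) stop("missing score for: ", paste(miss, collapse = ", "))
  miss2 <- setdiff(names(scores), records$id)
  if (length(miss2) > 0) stop("missing quality record for: ",
                              paste(miss2, collapse = ", "))
  ids <- sort(records$id)
  data.frame(id = ids,
             irms_A = records$irms_A[match(ids, records$id)],
             dg_off = unname(scores[ids]),
             stringsAsFactors = FALSE)
}

#' Enrichment report over a ranking
#'
#' Per-category composition, mean Recall and Precision for the full decoy
#' set and for each top-k selection (plus the top half), and the target
#' difficulty (fraction of acceptable-or-better structures in the full
#' set).
#'
#' @param ranking A `dock_ranking`.
#' @param records Quality records with `id`, `category`, `fnat`, `fnonnat`.
#' @param topk Selection sizes (default 1, 5, 10, 20, 100).
#' @return An `enrichment_report`: list with `difficulty`, `selections`
#'   (data.frame: one row per selection with category fractions, recall,
#'   precision, n) .
#' @export
enrichment_report <- function(ranking, records, topk = c(1, 5, 10, 20, 100)) {
  stopifnot(inherits(ranking, "dock_ranking"))
  check_records(records)
  n <- nrow(ranking)
  sels <- c(list(full = ranking$id,
                 top_half = top_k(ranking, ceiling(n / 2))),
            stats::setNames(lapply(topk, function(k) top_k(ranking, k)),
                            paste0("top_", topk)))
  rows <- lapply(names(sels), function(nm) {
    fr <- enrichment(sels[[nm]], records)
    rp <- recall_precision(sels[[nm]], records)
    data.frame(selection = nm, n = length(sels[[nm]]),
               High = unname(fr["High"]), Medium = unname(fr["Medium"]),
               Acceptable = unname(fr["Acceptable"]),
               Incorrect = unname(fr["Incorrect"]),
               acceptable_or_better = sum(fr[c("High", "Medium", "Acceptable")]),
               recall = unname(rp["recall"]), precision = unname(rp["precision"]),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(difficulty = tab$acceptable_or_better[tab$selection == "full"],
                 selections = tab),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf("Target difficulty (acceptable-or-better fraction): %.3f\n",
              x$difficulty))
  df <- x$selections
  df[, 3:9] <- round(df[, 3:9], 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.enrichment_report <- function(x, ...) {
  df <- x$selections
  m <- t(as.matrix(df[, c("High", "Medium", "Acceptable", "Incorrect")]))
  colnames(m) <- df$selection
  graphics::barplot(m, col = c("firebrick", "orange", "gold", "grey70"),
                    legend.text = rownames(m), las = 2,
                    ylab = "fraction of selection", ...)
  invisible(x)
}
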