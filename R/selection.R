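#' Fit multicollinearity pruning and z-score normalization on training data
#'
#' Zero-variance features (population variance below 1e-12) are dropped first
#' unconditionally. The absolute Pearson correlation matrix of the remaining
#' features is then traversed along the upper triangle in panel order:
#' whenever `|r(i, j)| > threshold` and both features are still kept, the
#' later-ordered feature `j` is dropped, recording `i` as the retained
#' partner. Finally z-score parameters (mean and population standard
#' deviation) are fitted on the kept features. Fitting never sees anything
#' but `train`, so held-out data cannot leak into the transform.
#'
#' @param train feature data.frame (an `id`/`label` column pair, if present,
#'   is ignored); at least 3 rows.
#' @param threshold absolute-correlation drop threshold in (0, 1\], default
#'   0.9.
#' @return a [SelectionState-class].
#' @examples
#' tab <- data.frame(a = c(1, 2, 3, 4), b = c(1.1, 2, 3.2, 4), c = c(4, 1, 3, 2))
#' keptFeatures(fitSelection(tab))
#' @export
fitSelection <- function(train, threshold = 0.9) {
  cols <- featureColumns(train)
  x <- as.matrix(train[, cols, drop = FALSE])
  if (nrow(x) < 3L) stop("need at least 3 training rows", call. = FALSE)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]", call. = FALSE)
  v <- apply(x, 2, function(col) mean((col - mean(col))^2))
  zeroVar <- cols[v < 1e-12]
  dropped <- data.frame(feature = zeroVar,
                        partner = rep(NA_character_, length(zeroVar)),
                        reason = rep("zero-variance", length(zeroVar)),
                        stringsAsFactors = FALSE)
  live <- setdiff(cols, zeroVar)
  if (length(live) == 0L) stop("all features dropped (zero variance)", call. = FALSE)
  if (length(live) > 1L) {
    r <- abs(stats::cor(x[, live, drop = FALSE]))
    keep <- rep(TRUE, length(live))
    for (i in seq_len(length(live) - 1L)) {
      if (!keep[i]) next
      for (j in seq(i + 1L, length(live))) {
        if (keep[j] && r[i, j] > threshold) {
          keep[j] <- FALSE
          dropped <- rbind(dropped, data.frame(
            feature = live[j], partner = live[i], reason = "collinear",
            stringsAsFactors = FALSE))
        }
      }
    }
    live <- live[keep]
  }
  if (length(live) == 0L) stop("all features dropped", call. = FALSE)
  mu <- colMeans(x[, live, drop = FALSE])
  sd <- apply(x[, live, drop = FALSE], 2, popSd)
  methods::new("SelectionState", keptFeatures = live, dropped = dropped,
               center = mu, scale = sd, threshold = threshold)
}

#' Apply a fitted selection state to a feature table
#'
#' Keeps only the retained features and z-scores each with the training
#' parameters. `id`/`label` columns are carried through unchanged.
#'
#' @param table feature data.frame containing every kept feature.
#' @param state a [SelectionState-class] from [fitSelection()].
#' @return data.frame with the kept, normalized feature columns.
#' @export
applySelection <- function(table, state) {
  missing <- setdiff(state@keptFeatures, names(table))
  if (length(missing))
    stop("table is missing kept feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  x <- as.matrix(table[, state@keptFeatures, drop = FALSE])
  z <- sweep(sweep(x, 2, state@center), 2, state@scale, "/")
  out <- as.data.frame(z)
  names(out) <- state@keptFeatures
  meta <- intersect(c("id", "label"), names(table))
  if (length(meta)) out <- cbind(table[, meta, drop = FALSE], out)
  rownames(out) <- NULL
  out
}

#' Serialize / restore a selection state as JSON
#'
#' @param state a [SelectionState-class].
#' @param path JSON file path.
#' @return `selectionFromJson` returns the restored [SelectionState-class].
#' @export
selectionToJson <- function(state, path) {
  jsonlite::write_json(list(
    kept = state@keptFeatures,
    dropped = state@dropped,
    center = as.list(state@center),
    scale = as.list(state@scale),
    threshold = state@threshold), path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}

#' @rdname selectionToJson
#' @export
selectionFromJson <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  dropped <- as.data.frame(j$dropped, stringsAsFactors = FALSE)
  if (nrow(dropped) == 0L)
    dropped <- data.frame(feature = character(0), partner = character(0),
                          reason = character(0), stringsAsFactors = FALSE)
  methods::new("SelectionState", keptFeatures = j$kept, dropped = dropped,
               center = unlist(j$center), scale = unlist(j$scale),
               threshold = j$threshold)
}
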