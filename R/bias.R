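#' Confusion table of 4-alternative categorization responses
#'
#' Counts of disgust/anger/fear/sad/no-response categorizations of one
#' observer's face stimuli, by body context. Context rows are body-emotion
#' labels; which row is the congruent context is determined by the face
#' emotion (for a disgust face, the disgust body is congruent and the anger
#' body incongruent).
#'
#' @param x either a matrix/data frame of counts with contexts as rows and
#'   response categories as columns (missing categories are filled with 0),
#'   or a trial-level data frame with columns `context` and `response`.
#' @param face_emotion the physical facial expression, `"disgust"` or
#'   `"anger"`.
#' @return object of class `"confusion_table"`.
#' @export
confusion_table <- function(x, face_emotion = c("disgust", "anger")) {
  face_emotion <- match.arg(face_emotion)
  resp_cats <- c("disgust", "anger", "fear", "sad", "no_response")
  if (is.data.frame(x) && all(c("context", "response") %in% names(x))) {
    resp <- ifelse(x$response == "none", "no_response", as.character(x$response))
    bad <- setdiff(unique(resp), resp_cats)
    if (length(bad))
      stop("unknown response label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    counts <- table(factor(x$context, levels = unique(x$context)),
                    factor(resp, levels = resp_cats))
    counts <- matrix(counts, nrow = nrow(counts),
                     dimnames = list(rownames(counts), resp_cats))
  } else {
    counts <- as.matrix(x)
    if (is.null(colnames(counts))) {
      if (!ncol(counts) %in% 4:5)
        stop("unnamed count matrices must have 4 or 5 columns ",
             "(disgust, anger, fear, sad[, no_response])", call. = FALSE)
      colnames(counts) <- resp_cats[seq_len(ncol(counts))]
    }
    missing_cols <- setdiff(resp_cats, colnames(counts))
    if (length(missing_cols)) {
      add <- matrix(0, nrow(counts), length(missing_cols),
                    dimnames = list(rownames(counts), missing_cols))
      counts <- cbind(counts, add)
    }
    counts <- counts[, resp_cats, drop = FALSE]
  }
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  structure(list(counts = counts, face_emotion = face_emotion),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat("Confusion table (face emotion:", x$face_emotion, ")\n")
  print(x$counts)
  invisible(x)
}

other_of_pair <- function(emotion) if (emotion == "disgust") "anger" else "disgust"

#' Correct-response proportions in congruent and incongruent contexts
#'
#' Restricted to disgust and anger responses within the disgust and anger
#' body contexts: the proportion of correct (face-emotion) responses relative
#' to all disgust-plus-anger responses in that context. Fear, sad and
#' no-response counts enter neither numerator nor denominator.
#'
#' @param table a [confusion_table()].
#' @return list with `p_con`, `p_incon` (proportions) and `n_con`, `n_incon`
#'   (the disgust+anger response counts used as denominators).
#' @export
context_proportions <- function(table) {
  stopifnot(inherits(table, "confusion_table"))
  face <- table$face_emotion
  con <- face
  incon <- other_of_pair(face)
  for (ctx in c(con, incon))
    if (!ctx %in% rownames(table$counts))
      stop("context '", ctx, "' missing from the confusion table", call. = FALSE)
  prop <- function(ctx) {
    n <- table$counts[ctx, "disgust"] + table$counts[ctx, "anger"]
    if (n == 0)
      stop("proportion undefined: no disgust or anger responses in the '",
           ctx, "' context", call. = FALSE)
    list(p = unname(table$counts[ctx, face] / n), n = as.integer(n))
  }
  p_c <- prop(con); p_i <- prop(incon)
  list(p_con = p_c$p, p_incon = p_i$p, n_con = p_c$n, n_incon = p_i$n)
}

#' Categorization Bias Index 1 (proportion ratio)
#'
#' Ratio of the correct-response proportions in the congruent and incongruent
#' contexts, `p_con / p_incon`. Values above 1 indicate a context-induced
#' bias away from the face emotion in the incongruent context. Being a ratio
#' it is undefined at `p_incon = 0` and sensitive to outliers, which is why
#' the z-based [bias_index_2()] is the robust companion measure.
#'
#' @param p_con,p_incon correct-response proportions from
#'   [context_proportions()].
#' @return positive ratio.
#' @export
bias_index_1 <- function(p_con, p_incon) {
  if (p_incon == 0)
    stop("Bias Index 1 is undefined at p_incon = 0; use bias_index_2()",
         call. = FALSE)
  p_con / p_incon
}

#' Categorization Bias Index 2 (z difference, d'-style)
#'
#' Difference of inverse-normal-transformed correct-response proportions,
#' `z(p_con) - z(p_incon)`. Extreme proportions of exactly 0 or 1 are
#' adjusted to `1/N` and `1 - 1/N` respectively before the transform, with
#' `N` the disgust+anger response count of that context (the denominator of
#' the proportion being adjusted).
#'
#' @param p_con,p_incon correct-response proportions.
#' @param n_con,n_incon the per-context disgust+anger response counts.
#' @return the index, with attribute `"adjusted"` flagging whether the 1/N
#'   rule fired.
#' @export
bias_index_2 <- function(p_con, p_incon, n_con, n_incon) {
  if (n_con < 1 || n_incon < 1)
    stop("Bias Index 2 undefined for empty contexts", call. = FALSE)
  adj <- function(p, n) {
    if (p == 0) 1 / n else if (p == 1) 1 - 1 / n else p
  }
  p_c <- adj(p_con, n_con); p_i <- adj(p_incon, n_incon)
  structure(qnorm(p_c) - qnorm(p_i),
            adjusted = (p_c != p_con) || (p_i != p_incon))
}

#' Both bias indices of a confusion table
#'
#' @param table a [confusion_table()].
#' @return list (`bias_indices`) with `index1` (`NA` when undefined),
#'   `index2`, `p_con`, `p_incon`, `n_con`, `n_incon` and the `adjusted`
#'   flag. Metadata records that `N` in the 1/N adjustment is the
#'   per-context disgust+anger response count.
#' @export
bias_indices <- function(table) {
  pr <- context_proportions(table)
  i1 <- if (pr$p_incon > 0) bias_index_1(pr$p_con, pr$p_incon) else NA_real_
  i2 <- bias_index_2(pr$p_con, pr$p_incon, pr$n_con, pr$n_incon)
  structure(list(index1 = i1, index2 = as.numeric(i2),
                 p_con = pr$p_con, p_incon = pr$p_incon,
                 n_con = pr$n_con, n_incon = pr$n_incon,
                 adjusted = attr(i2, "adjusted"),
                 n_definition = "disgust+anger responses per context"),
            class = "bias_indices")
}

#' @export
print.bias_indices <- function(x, ...) {
  cat(sprintf("Bias indices: index1 = %s, index2 = %.4f%s\n",
              if (is.na(x$index1)) "undefined" else format(x$index1, digits = 4),
              x$index2, if (x$adjusted) " (1/N adjusted)" else ""))
  cat(sprintf("  p_con = %.3f (N = %d), p_incon = %.3f (N = %d)\n",
              x$p_con, x$n_con, x$p_incon, x$n_incon))
  invisible(x)
}

#' Read trial-level categorization CSV
#'
#' Dialect: `observer_id,context,face_emotion,response`, with `context` in
#' disgust/anger/fear/sad and `response` in disgust/anger/fear/sad/none.
#'
#' @param path file path.
#' @return data frame of validated trials.
#' @export
read_categorization_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("observer_id", "context", "face_emotion", "response")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("categorization CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  check_values <- function(col, allowed) {
    bad <- which(!d[[col]] %in% allowed)
    if (length(bad))
      stop(sprintf("invalid '%s' value '%s' at line %d of %s", col,
                   d[[col]][bad[1]], bad[1] + 1L, path), call. = FALSE)
  }
  check_values("context", c("disgust", "anger", "fear", "sad"))
  check_values("face_emotion", c("disgust", "anger"))
  check_values("response", c("disgust", "anger", "fear", "sad", "none"))
  d
}

#' Export a confusion table as JSON, keyed by context
#'
#' @param table a [confusion_table()].
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @export
confusion_to_json <- function(table, path = NULL) {
  stopifnot(inherits(table, "confusion_table"))
  by_ctx <- lapply(seq_len(nrow(table$counts)), function(i)
    as.list(table$counts[i, ]))
  names(by_ctx) <- rownames(table$counts)
  js <- jsonlite::toJSON(list(face_emotion = table$face_emotion,
                              contexts = by_ctx),
                         auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
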