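#' SMOTE minority-class oversampling
#'
#' Synthetic Minority Over-sampling: each synthetic record is a convex
#' combination `x + u * (x_nn - x)`, `u ~ Uniform(0, 1)`, of a minority
#' record and one of its `k_neighbors` nearest same-class neighbours
#' (Euclidean metric on the 9 features, in whatever space the input is
#' expressed). Original records are preserved verbatim and synthetic rows
#' are flagged in the result's `origin` field. Majority classes are never
#' down-sampled.
#'
#' @param data A [feature_matrix()].
#' @param k_neighbors Number of same-class nearest neighbours to draw from
#'   (default 5, internally capped at class size - 1).
#' @param target `"balance"` (every class is raised to the majority count)
#'   or a named per-class vector of target counts (never below the current
#'   counts).
#' @param seed Optional integer seed for deterministic output.
#' @param on_singleton What to do when a class slated for oversampling has
#'   fewer than 2 records: `"error"` (default) or `"skip"` (leave the class
#'   as-is with a warning; used by the federated pipeline where tiny
#'   non-IID shards are expected).
#' @return A `feature_matrix` containing all original rows followed by the
#'   synthetic rows. If no synthesis is needed the input is returned
#'   unchanged.
#' @export
smote_oversample <- function(data, k_neighbors = 5, target = "balance",
                             seed = NULL, on_singleton = c("error", "skip")) {
  stopifnot(inherits(data, "feature_matrix"))
  on_singleton <- match.arg(on_singleton)
  if (k_neighbors < 1) stop("k_neighbors must be >= 1", call. = FALSE)
  counts <- class_counts(data)
  if (identical(target, "balance")) {
    tgt <- stats::setNames(rep(max(counts), 3), class_labels())
    tgt[counts == 0] <- 0  # absent classes cannot be synthesized
  } else {
    tgt <- counts
    tgt[names(target)] <- pmax(target, counts[names(target)])
  }
  need <- pmax(as.integer(tgt) - as.integer(counts), 0L)
  names(need) <- class_labels()
  if (sum(need) == 0) return(data)

  run <- function() {
    syn_vals <- list()
    syn_labels <- integer(0)
    for (code in 0:2) {
      cl <- class_labels()[code + 1L]
      n_syn <- need[[cl]]
      if (n_syn == 0) next
      idx <- which(data$labels == code)
      if (length(idx) < 2) {
        msg <- paste0("class ", sQuote(cl), " has ", length(idx),
                      " record(s); SMOTE needs at least 2 to interpolate")
        if (on_singleton == "error") stop(msg, call. = FALSE)
        warning(msg, " - class left as-is", call. = FALSE)
        next
      }
      xc <- data$values[idx, , drop = FALSE]
      k <- min(k_neighbors, nrow(xc) - 1L)
      d <- as.matrix(stats::dist(xc))
      diag(d) <- Inf
      nn_raw <- vapply(seq_len(nrow(xc)),
                       function(i) order(d[i, ])[seq_len(k)], integer(k))
      nn <- if (k == 1) matrix(nn_raw, ncol = 1) else t(nn_raw)
      base <- sample.int(nrow(xc), n_syn, replace = TRUE)
      pick <- sample.int(k, n_syn, replace = TRUE)
      nbr <- nn[cbind(base, pick)]
      u <- stats::runif(n_syn)
      syn_vals[[cl]] <- xc[base, , drop = FALSE] +
        u * (xc[nbr, , drop = FALSE] - xc[base, , drop = FALSE])
      syn_labels <- c(syn_labels, rep(code, n_syn))
    }
    if (length(syn_vals) == 0) return(data)
    n0 <- n_records(data)
    n_syn_total <- length(syn_labels)
    vals <- rbind(data$values, do.call(rbind, syn_vals))
    labels <- c(data$labels, syn_labels)
    sids <- NULL
    if (!is.null(data$subject_ids)) {
      sids <- c(data$subject_ids,
                sprintf("synthetic_%05d", seq_len(n_syn_total)))
    }
    origin <- c(
      if (is.null(data$origin)) rep("original", n0) else data$origin,
      rep("synthetic", n_syn_total)
    )
    feature_matrix(vals, labels, subject_ids = sids, origin = origin)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}
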