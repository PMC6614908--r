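#' Forward-selection conditional analysis
#'
#' Detects multiple independent association signals: starting from the
#' unconditional scan, while the smallest (conditional) p-value is below the
#' genome-wide threshold the corresponding top site joins the conditioned
#' set and the scan is repeated conditioning on all chosen sites. A
#' candidate whose dosage is collinear (r-squared >= `collinearity_cap`)
#' with an already-chosen site is skipped with a warning and the next-ranked
#' candidate is taken.
#'
#' @param data a [geno_dataset()].
#' @param y phenotype (`pheno_sim` or numeric).
#' @param threshold significance threshold (default 5e-8).
#' @param collinearity_cap maximum r-squared tolerated between a candidate
#'   and any chosen signal (default 0.9).
#' @param max_rounds safety cap on selection rounds.
#' @return A `conditional_result`: list with `signals` (ordered site ids),
#'   `rounds` (data frame: round, conditioned set, top site, p),
#'   `method = "forward"`, `threshold`.
#' @export
forward_selection <- function(data, y, threshold = 5e-8,
                              collinearity_cap = 0.9, max_rounds = 50) {
  y <- as_pheno_values(y)
  signals <- character(0)
  rounds <- list()
  for (round in seq_len(max_rounds)) {
    res <- conditional_regression(data, y, signals,
                                  collinearity_cap = 1)  # screen below
    ranking <- attr(res, "ranking")
    p <- stats::setNames(res$p_value, res$site)
    top <- NA_character_; top_p <- NA_real_
    for (cand in ranking) {
      if (p[[cand]] >= threshold) break
      if (passes_collinearity(data, cand, signals, collinearity_cap)) {
        top <- cand; top_p <- p[[cand]]
        break
      }
      warning("forward_selection: skipping ", cand,
              " (collinear with a chosen signal)")
    }
    rounds[[round]] <- data.frame(
      round = round,
      conditioned = paste(signals, collapse = ","),
      top_site = if (is.na(top)) ranking[1] else top,
      p_value = if (is.na(top)) unname(p[ranking[1]]) else top_p,
      added = !is.na(top),
      stringsAsFactors = FALSE)
    if (is.na(top)) break
    signals <- c(signals, top)
  }
  structure(list(signals = signals,
                 rounds = do.call(rbind, rounds),
                 method = "forward", threshold = threshold),
            class = "conditional_result")
}

passes_collinearity <- function(data, cand, chosen, cap) {
  if (!length(chosen)) return(TRUE)
  xc <- site_dosage(data, cand)
  for (s in chosen) {
    r2 <- suppressWarnings(stats::cor(xc, site_dosage(data, s))^2)
    if (is.finite(r2) && r2 >= cap) return(FALSE)
  }
  TRUE
}

#' Stepwise (forward-backward) joint conditional analysis
#'
#' The conditional-and-joint selection scheme: a forward step adds the best
#' remaining site if its conditional p-value is below `threshold` (screened
#' for collinearity against the chosen set); a backward step refits all
#' chosen sites jointly and drops any member whose joint p-value is at or
#' above `threshold` (worst first). Steps alternate until the chosen set is
#' stable; cycling beyond `max_rounds` raises an error reporting the sets.
#'
#' @inheritParams forward_selection
#' @return A `conditional_result` with `method = "stepwise_joint"`.
#' @export
stepwise_joint_selection <- function(data, y, threshold = 5e-8,
                                     collinearity_cap = 0.9,
                                     max_rounds = 50) {
  y <- as_pheno_values(y)
  signals <- character(0)
  rounds <- list()
  seen <- character(0)
  for (round in seq_len(max_rounds)) {
    changed <- FALSE
    # forward step
    res <- conditional_regression(data, y, signals, collinearity_cap = 1)
    ranking <- attr(res, "ranking")
    p <- stats::setNames(res$p_value, res$site)
    added <- NA_character_
    for (cand in ranking) {
      if (p[[cand]] >= threshold) break
      if (passes_collinearity(data, cand, signals, collinearity_cap)) {
        added <- cand
        break
      }
      warning("stepwise_joint_selection: skipping ", cand,
              " (collinear with a chosen signal)")
    }
    if (!is.na(added)) {
      signals <- c(signals, added)
      changed <- TRUE
    }
    # backward step: joint fit of chosen set
    dropped <- character(0)
    while (length(signals) > 1) {
      xj <- data$dosages[, site_index(data, signals), drop = FALSE]
      fit <- summary(stats::lm(y ~ xj))$coefficients
      pj <- fit[-1, 4]
      worst <- which.max(pj)
      if (pj[worst] >= threshold) {
        dropped <- c(dropped, signals[worst])
        signals <- signals[-worst]
        changed <- TRUE
      } else break
    }
    rounds[[round]] <- data.frame(
      round = round,
      conditioned = paste(signals, collapse = ","),
      top_site = if (is.na(added)) NA_character_ else added,
      p_value = if (is.na(added)) NA_real_ else unname(p[added]),
      added = !is.na(added),
      stringsAsFactors = FALSE)
    state <- paste(sort(signals), collapse = "|")
    if (!changed) break
    if (state %in% seen && round > 2) {
      stop("stepwise_joint_selection: selection is cycling between sets: ",
           paste(unique(c(seen, state)), collapse = " / "))
    }
    seen <- c(seen, state)
    if (round == max_rounds) {
      stop("stepwise_joint_selection: no stable set within max_rounds")
    }
  }
  structure(list(signals = signals,
                 rounds = do.call(rbind, rounds),
                 method = "stepwise_joint", threshold = threshold),
            class = "conditional_result")
}

#' @export
print.conditional_result <- function(x, ...) {
  cat(sprintf("<conditional_result:%s> %d signal(s): %s\n",
              x$method, length(x$signals),
              paste(x$signals, collapse = ", ")))
  invisible(x)
}
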