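# Dual-gated survival classification and regression tree.
#
# Greedy binary recursive partitioning on a censored time-to-event outcome
# in which a split is accepted only when (i) the Cox score test of the
# split indicator and (ii) the log-rank test on the resulting children are
# both significant at `alpha`, and both children hold at least `min_node`
# subjects. A branch ends when no candidate passes the dual gate. Each
# node carries Kaplan-Meier probabilities of remaining event-free at the
# landmark months.

#' Candidate predictor sets for the two model variants
#'
#' Age at first symptom and disease duration are linear complements of age
#' at baseline, so they are never offered to the tree together: variant A
#' uses disease duration, variant B age at first symptom, alongside the
#' common predictors (sex, index-relapse phenotype, pre-baseline relapse
#' count, dominant symptom, baseline EDSS, most affected KFS, prior DMT,
#' age at baseline).
#'
#' @param variant `"A"` or `"B"`.
#' @return Character vector of covariate names as produced by
#'   [cohort_covariates()].
#' @export
cdaf_candidates <- function(variant = c("A", "B")) {
  variant <- match.arg(variant)
  common <- c("poly", "relapse_count_2y", "sex", "dominant_symptom",
              "baseline_edss", "most_affected_kfs", "prior_dmt",
              "age_at_baseline")
  c(common, if (variant == "A") "disease_duration" else "age_at_first_symptom")
}

#' Fit a dual-gated survival tree
#'
#' @param formula A formula `survival::Surv(time, event) ~ v1 + v2 + ...`
#'   naming the candidate split variables. The declaration order on the
#'   right-hand side is the deterministic tie-break when two variables
#'   reach the same score-test p-value.
#' @param data Data frame with the follow-up time, event indicator and
#'   candidate variables (one row per subject).
#' @param alpha Significance level both gates must pass (default 0.05).
#' @param min_node Minimum subjects in each child of a split (default 5).
#' @param landmarks Months at which node-level Kaplan-Meier event-free
#'   probabilities are reported (default 6, 12, 18, 24).
#' @param max_depth Optional safety cap on tree depth (default unlimited;
#'   the significance gates are the intended stopping rule).
#' @param ties Tie handling for the Cox score test (`"efron"` default).
#' @return Object of class `dgcart` with elements `root` (nested node
#'   structure), `variables`, `alpha`, `min_node`, `landmarks`, `n`,
#'   `n_events`.
#' @examples
#' \donttest{
#' coh <- simulate_cohort(cohort_config(n_subjects = 150, seed = 7))
#' d <- merge(derive_endpoints(coh, "cDAF"), cohort_covariates(coh))
#' fit <- dgcart(survival::Surv(time, event) ~ poly + relapse_count_2y +
#'                 baseline_edss, data = d)
#' print(fit)
#' }
#' @export
dgcart <- function(formula, data, alpha = 0.05, min_node = 5,
                   landmarks = c(6, 12, 18, 24), max_depth = Inf,
                   ties = "efron") {
  stopifnot(inherits(formula, "formula"), is.data.frame(data),
            alpha > 0, alpha < 1, min_node >= 1)
  if (!nrow(data)) stop("empty dataset")
  vars <- attr(stats::terms(formula, data = data), "term.labels")
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop("unknown candidate variable(s): ", paste(miss, collapse = ", "))
  if (all(c("disease_duration", "age_at_first_symptom") %in% vars))
    stop("disease_duration and age_at_first_symptom are collinear with ",
         "age_at_baseline; use one per model variant")
  y <- eval(formula[[2]], envir = data, enclos = environment(formula))
  if (!survival::is.Surv(y))
    stop("left-hand side must be a survival::Surv object")
  d <- data.frame(time = as.numeric(y[, "time"]),
                  event = as.integer(y[, "status"]))
  for (v in vars) d[[v]] <- data[[v]]

  next_id <- 0L
  build <- function(d, depth) {
    next_id <<- next_id + 1L
    node <- list(id = next_id, n = nrow(d), n_events = sum(d$event),
                 depth = depth,
                 km = node_summary(d$time, d$event, landmarks),
                 split = NULL, children = NULL)
    if (depth >= max_depth || nrow(d) < 2 * min_node || sum(d$event) == 0)
      return(node)
    best <- NULL
    for (v in vars) {
      bs <- best_binary_split(d, v, min_size = min_node, ties = ties)
      if (is.null(bs)) next
      if (is.null(best) || bs$score_p < best$score_p) best <- bs
    }
    if (is.null(best) || !(best$score_p < alpha) ||
        !(best$logrank_p < alpha))
      return(node)
    ind <- best$indicator
    node$split <- best[c("variable", "split", "label", "score_p",
                         "score_stat", "logrank_p")]
    node$children <- list(left = build(d[ind == 0, , drop = FALSE],
                                       depth + 1),
                          right = build(d[ind == 1, , drop = FALSE],
                                        depth + 1))
    node
  }
  root <- build(d, 0L)
  structure(list(root = root, variables = vars, alpha = alpha,
                 min_node = min_node, landmarks = landmarks,
                 max_depth = max_depth, ties = ties,
                 n = nrow(d), n_events = sum(d$event),
                 call = match.call()),
            class = "dgcart")
}

#' Kaplan-Meier landmark summary of a node
#'
#' Event-free probabilities at the landmark months within one subject
#' subset, read right-continuously from the Kaplan-Meier step function
#' (not raw fractions, so censored subjects contribute risk time).
#'
#' @param time,event Follow-up and event indicator of the node's subjects.
#' @param landmarks Months.
#' @return Named numeric vector of probabilities.
#' @export
node_summary <- function(time, event, landmarks = c(6, 12, 18, 24)) {
  stopifnot(length(time) >= 1)
  curve <- km_estimate(time, event)
  stats::setNames(km_prob_at(curve, landmarks),
                  paste0("month", landmarks))
}

# ---- methods ----------------------------------------------------------

node_line <- function(node, label) {
  km24 <- node$km[length(node$km)]
  sprintf("%s n=%d events=%d  %s=%.1f%%", label, node$n, node$n_events,
          names(km24), 100 * km24)
}

print_node <- function(node, indent, label) {
  cat(strrep("  ", indent), node_line(node, label), "\n", sep = "")
  if (!is.null(node$split)) {
    s <- node$split
    cat(strrep("  ", indent),
        sprintf("  split: %s (score p=%.3g, log-rank p=%.3g)\n",
                s$label, s$score_p, s$logrank_p), sep = "")
    print_node(node$children$left, indent + 1, sprintf("[not %s]", s$label))
    print_node(node$children$right, indent + 1, sprintf("[%s]", s$label))
  }
}

#' @export
print.dgcart <- function(x, ...) {
  cat(sprintf(paste0("Dual-gated survival tree: n = %d, events = %d, ",
                     "alpha = %g, min node = %d\n"),
              x$n, x$n_events, x$alpha, x$min_node))
  print_node(x$root, 0, "<root>")
  invisible(x)
}

collect_leaves <- function(node, path = "<root>") {
  if (is.null(node$split))
    return(list(list(id = node$id, path = path, n = node$n,
                     n_events = node$n_events, km = node$km)))
  s <- node$split
  c(collect_leaves(node$children$left, paste0(path, " & !(", s$label, ")")),
    collect_leaves(node$children$right, paste0(path, " & (", s$label, ")")))
}

#' @export
summary.dgcart <- function(object, ...) {
  leaves <- collect_leaves(object$root)
  tab <- do.call(rbind, lapply(leaves, function(l)
    cbind(data.frame(leaf = l$id, n = l$n, events = l$n_events,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(l$km)),
          data.frame(path = sub("^<root> & ", "", l$path)))))
  rownames(tab) <- NULL
  structure(list(leaves = tab, n = object$n, n_events = object$n_events,
                 alpha = object$alpha), class = "summary.dgcart")
}

#' @export
print.summary.dgcart <- function(x, ...) {
  cat(sprintf("Leaves of dual-gated survival tree (n = %d, events = %d):\n",
              x$n, x$n_events))
  print(x$leaves, row.names = FALSE)
  invisible(x)
}

#' Assign subjects to tree leaves
#'
#' @param object A fitted [dgcart()].
#' @param newdata Data frame with the candidate variables.
#' @param type `"leaf"` for leaf node ids, `"prob"` for the assigned
#'   leaf's landmark event-free probabilities (matrix, one row per
#'   subject).
#' @param ... Unused.
#' @return Integer vector of leaf ids, or a numeric matrix.
#' @export
predict.dgcart <- function(object, newdata,
                           type = c("leaf", "prob"), ...) {
  type <- match.arg(type)
  descend <- function(node, row) {
    if (is.null(node$split)) return(node)
    x <- row[[node$split$variable]]
    ind <- split_indicator(x, node$split$split)
    descend(if (ind == 1) node$children$right else node$children$left, row)
  }
  leaves <- lapply(seq_len(nrow(newdata)), function(i)
    descend(object$root, newdata[i, , drop = FALSE]))
  if (type == "leaf") return(vapply(leaves, `[[`, integer(1), "id"))
  out <- do.call(rbind, lapply(leaves, `[[`, "km"))
  rownames(out) <- NULL
  out
}

#' Plot a dual-gated survival tree
#'
#' Simple base-graphics rendering: nodes as boxes annotated with size and
#' the month-24 event-free probability, splits as labelled edges.
#'
#' @param x A fitted [dgcart()].
#' @param ... Unused.
#' @export
plot.dgcart <- function(x, ...) {
  depth_of <- function(node) {
    if (is.null(node$split)) return(node$depth)
    max(depth_of(node$children$left), depth_of(node$children$right))
  }
  dmax <- max(1, depth_of(x$root))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 1), ylim = c(-0.05, 1.05))
  draw <- function(node, x0, x1, y) {
    xm <- (x0 + x1) / 2
    km24 <- node$km[length(node$km)]
    graphics::rect(xm - 0.07, y - 0.035, xm + 0.07, y + 0.035,
                   col = "grey95")
    graphics::text(xm, y, sprintf("n=%d\n%.0f%%", node$n, 100 * km24),
                   cex = 0.7)
    if (!is.null(node$split)) {
      y2 <- y - 1 / (dmax + 1)
      for (side in c("left", "right")) {
        child <- node$children[[side]]
        cx <- if (side == "left") (x0 + xm) / 2 else (xm + x1) / 2
        graphics::segments(xm, y - 0.035, cx, y2 + 0.035)
        if (side == "right")
          graphics::text((xm + cx) / 2, (y + y2) / 2, node$split$label,
                         cex = 0.6, pos = 4)
        draw(child, if (side == "left") x0 else xm,
             if (side == "left") xm else x1, y2)
      }
    }
  }
  draw(x$root, 0, 1, 1)
  graphics::title(main = "Dual-gated survival tree")
  invisible(x)
}

# ---- serialization ----------------------------------------------------

node_to_list <- function(node) {
  out <- list(id = node$id, n = node$n, n_events = node$n_events,
              depth = node$depth, km = as.list(node$km))
  if (!is.null(node$split)) {
    s <- node$split
    out$split <- list(variable = s$variable, type = s$split$type,
                      threshold = s$split$threshold,
                      levels = s$split$levels, label = s$label,
                      score_p = s$score_p, score_stat = s$score_stat,
                      logrank_p = s$logrank_p)
    out$split <- out$split[!vapply(out$split, is.null, logical(1))]
    out$children <- list(left = node_to_list(node$children$left),
                         right = node_to_list(node$children$right))
  }
  out
}

#' Lossless nested serialization of a tree
#'
#' `render_tree()` converts a fitted tree into a plain nested list
#' (splits, p-values, node sizes, landmark probabilities) suitable for
#' JSON output; `write_tree_json()`/`read_tree_json()` round-trip it to
#' disk with full numeric precision.
#'
#' @param tree A fitted [dgcart()].
#' @return For `render_tree`, a nested list with elements `alpha`,
#'   `min_node`, `landmarks`, `variables`, `root`.
#' @export
render_tree <- function(tree) {
  stopifnot(inherits(tree, "dgcart"))
  list(alpha = tree$alpha, min_node = tree$min_node,
       landmarks = as.list(tree$landmarks),
       variables = as.list(tree$variables),
       n = tree$n, n_events = tree$n_events,
       root = node_to_list(tree$root))
}

#' @rdname render_tree
#' @param path File path for the JSON document.
#' @export
write_tree_json <- function(tree, path) {
  jsonlite::write_json(render_tree(tree), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname render_tree
#' @export
read_tree_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
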