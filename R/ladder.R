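#' Define the anchoring of a ladder fit
#'
#' A relative scale from pairwise differences is determined only up to an
#' additive constant; anchoring fixes it.  Three modes are supported:
#' \describe{
#'   \item{\code{fixed_single}}{one node pinned to a reference value (e.g. a
#'     relative scale with picric acid set to 0).}
#'   \item{\code{offset_multi}}{several nodes carry external reference values
#'     (e.g. quantum-chemically computed pKa values); the relative scale is
#'     fitted first and then shifted by the offset minimising the sum of
#'     squared differences to the references, which is their mean difference.}
#'   \item{\code{bridging}}{identical arithmetic to \code{offset_multi}, used
#'     when the references are bridging solutions of known aqueous-aligned
#'     unified acidity; results are then on the pH_abs(H2O) scale.}
#' }
#'
#' @param values named numeric vector: node id -> reference value.
#' @param mode anchoring mode.
#' @return list of class \code{"anchor_set"}.
#' @export
anchor_set <- function(values, mode = c("fixed_single", "offset_multi", "bridging")) {
  mode <- match.arg(mode)
  if (length(values) < 1 || is.null(names(values)) || any(names(values) == ""))
    stop("anchors must be a named numeric vector with at least one entry")
  if (any(!is.finite(values))) stop("anchor values must be finite")
  dup <- duplicated(names(values))
  if (any(dup)) {
    agree <- vapply(unique(names(values)[dup]), function(nd) {
      v <- values[names(values) == nd]; max(v) - min(v) < 1e-12
    }, logical(1))
    if (!all(agree)) stop("duplicate contradictory anchor values for: ",
                          paste(unique(names(values)[dup][!agree]), collapse = ", "))
    values <- values[!dup]
  }
  if (mode == "fixed_single" && length(values) != 1)
    stop("fixed_single anchoring pins exactly one node")
  structure(list(mode = mode, values = values), class = "anchor_set")
}

check_measurements <- function(m) {
  need <- c("node_a", "node_b", "delta")
  if (!all(need %in% names(m))) stop("measurements need columns node_a, node_b, delta")
  m$node_a <- as.character(m$node_a)
  m$node_b <- as.character(m$node_b)
  if (any(m$node_a == m$node_b)) stop("self-loop measurements are not allowed")
  if (any(!is.finite(m$delta))) stop("all deltas must be finite")
  if (is.null(m$kind)) m$kind <- "pK_ip"
  if (is.null(m$source)) m$source <- ""
  m
}

# components of the measurement graph, with all anchor nodes merged into one
# ground vertex (a scale is identifiable once each component touches ground)
graph_components <- function(nodes, edges_a, edges_b, anchored) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges_a, to = edges_b, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  if (length(anchored) > 1) {
    extra <- cbind(anchored[1], anchored[-1])
    g <- igraph::add_edges(g, t(as.matrix(apply(extra, 2, as.character))))
  }
  igraph::components(g)
}

assert_connected <- function(nodes, edges_a, edges_b, anchored) {
  comp <- graph_components(nodes, edges_a, edges_b, anchored)
  if (comp$no > 1) {
    grp <- split(nodes, comp$membership[nodes])
    stop("measurement graph is disconnected; components: ",
         paste(vapply(grp, function(x) paste0("{", paste(x, collapse = ","), "}"),
                      character(1)), collapse = " "))
  }
  invisible(TRUE)
}

# core least-squares solve with a set of pinned node values
solve_pinned <- function(meas, pinned) {
  nodes <- sort(unique(c(meas$node_a, meas$node_b, names(pinned))))
  free <- setdiff(nodes, names(pinned))
  values <- setNames(numeric(length(nodes)), nodes)
  values[names(pinned)] <- pinned
  if (length(free) > 0) {
    X <- matrix(0, nrow(meas), length(free), dimnames = list(NULL, free))
    y <- meas$delta
    for (i in seq_len(nrow(meas))) {
      a <- meas$node_a[i]; b <- meas$node_b[i]
      if (a %in% free) X[i, a] <- X[i, a] - 1 else y[i] <- y[i] + pinned[a]
      if (b %in% free) X[i, b] <- X[i, b] + 1 else y[i] <- y[i] - pinned[b]
    }
    fit <- lm.fit(X, y)
    if (fit$rank < length(free))
      stop("normal equations are singular; the measurement graph is not rigid")
    values[free] <- fit$coefficients
  }
  resid <- meas$delta - (values[meas$node_b] - values[meas$node_a])
  list(values = values, residuals = unname(resid), n_free = length(free))
}

#' Fit an acidity ladder by least squares
#'
#' Assigns one scale value per node (acid or buffer solution) from a graph of
#' pairwise difference measurements by minimising
#' \deqn{SS = \sum_i \left\{\Delta_i - [x(b_i) - x(a_i)]\right\}^2}
#' with the anchoring of \code{anchors} imposed.  The internal scatter of the
#' scale is summarised by the consistency standard deviation
#' \eqn{s = \sqrt{SS / (n_m - n_c)}}, where \eqn{n_m} counts included
#' measurements and \eqn{n_c} the fitted parameters.
#'
#' When \code{exclude_threshold} is set, measurement series that are strongly
#' inconsistent with the rest of the ladder are removed iteratively: refit,
#' find the worst absolute residual, exclude that edge if it reaches the
#' threshold, and repeat until no residual reaches it or a removal would
#' disconnect the graph (ties broken by input order; excluded edges are kept
#' in the report).
#'
#' @param measurements data frame with columns \code{node_a}, \code{node_b},
#'   \code{delta} (value of node_b minus node_a, pK or pH units) and optional
#'   \code{kind}, \code{source}, \code{excluded}.
#' @param anchors an \code{\link{anchor_set}}.
#' @param exclude_threshold absolute-residual threshold for iterative
#'   exclusion (pK/pH units), or \code{NULL} (no exclusion).  The
#'   potentiometric ladder used 0.75.
#' @param nc_counts_anchors if \code{TRUE}, count every assigned node value in
#'   \eqn{n_c} (the alternative reading of the degrees-of-freedom convention);
#'   default counts only freely fitted parameters (free nodes, plus one for
#'   the offset in \code{offset_multi}/\code{bridging} mode).
#' @param weights optional per-measurement weights (default unweighted).
#' @return object of class \code{"ladder_fit"}: assigned \code{values},
#'   per-measurement table with residuals and inclusion flags, \code{s},
#'   \code{SS}, \code{n_m}, \code{n_c}, the fitted \code{offset} (anchoring
#'   shift, if any) and bookkeeping.  Methods: \code{print}, \code{summary},
#'   \code{coef}, \code{residuals}, \code{fitted}, \code{predict},
#'   \code{plot}.
#' @examples
#' m <- data.frame(node_a = c("a", "b", "a"), node_b = c("b", "c", "c"),
#'                 delta = c(1.0, 1.0, 2.1))
#' fit <- fit_ladder(m, anchor_set(c(a = 0)))
#' coef(fit)
#' consistency_s(fit)
#' @export
fit_ladder <- function(measurements, anchors, exclude_threshold = NULL,
                       nc_counts_anchors = FALSE, weights = NULL) {
  stopifnot(inherits(anchors, "anchor_set"))
  meas <- check_measurements(as.data.frame(measurements))
  if (is.null(meas$excluded)) meas$excluded <- FALSE
  if (!is.null(weights)) {
    if (length(weights) != nrow(meas) || any(weights <= 0))
      stop("weights must be positive, one per measurement")
  } else weights <- rep(1, nrow(meas))
  present <- names(anchors$values) %in% unique(c(meas$node_a, meas$node_b))
  if (!any(present))
    stop("anchor nodes absent from the measurement graph: ",
         paste(names(anchors$values), collapse = ", "))
  if (!all(present)) {
    if (anchors$mode == "fixed_single")
      stop("pinned anchor node absent from the measurement graph: ",
           names(anchors$values)[!present])
    warning("dropping anchor nodes absent from the graph: ",
            paste(names(anchors$values)[!present], collapse = ", "))
    anchors$values <- anchors$values[present]
  }
  nodes <- sort(unique(c(meas$node_a, meas$node_b, names(anchors$values))))

  fit_once <- function(include) {
    mi <- meas[include, , drop = FALSE]
    wi <- weights[include]
    assert_connected(nodes, mi$node_a, mi$node_b, names(anchors$values))
    mw <- mi
    sw <- sqrt(wi)
    # weighted LS via row scaling of the incidence system
    if (any(sw != 1)) {
      pin <- if (anchors$mode == "fixed_single") anchors$values else
        setNames(0, names(anchors$values)[1])
      free <- setdiff(nodes, names(pin))
      X <- matrix(0, nrow(mw), length(free), dimnames = list(NULL, free))
      y <- mw$delta
      for (i in seq_len(nrow(mw))) {
        a <- mw$node_a[i]; b <- mw$node_b[i]
        if (a %in% free) X[i, a] <- -1 else y[i] <- y[i] + pin[a]
        if (b %in% free) X[i, b] <- 1 else y[i] <- y[i] - pin[b]
      }
      cf <- lm.fit(X * sw, y * sw)$coefficients
      values <- setNames(numeric(length(nodes)), nodes)
      values[names(pin)] <- pin
      values[free] <- cf
      sol <- list(values = values,
                  residuals = unname(mw$delta - (values[mw$node_b] - values[mw$node_a])),
                  n_free = length(free))
    } else {
      pin <- if (anchors$mode == "fixed_single") anchors$values else
        setNames(0, names(anchors$values)[1])
      sol <- solve_pinned(mw, pin)
    }
    sol
  }

  include <- !meas$excluded
  repeat {
    sol <- fit_once(include)
    if (is.null(exclude_threshold)) break
    worst <- which.max(abs(sol$residuals))
    if (length(worst) == 0 || abs(sol$residuals[worst]) < exclude_threshold) break
    idx_all <- which(include)[worst]
    trial <- include; trial[idx_all] <- FALSE
    if (sum(trial) == 0) break
    comp <- graph_components(nodes, meas$node_a[trial], meas$node_b[trial],
                             names(anchors$values))
    if (comp$no > 1) {
      warning("excluding the worst measurement (|residual| = ",
              signif(abs(sol$residuals[worst]), 3),
              ") would disconnect the graph; stopping exclusion")
      break
    }
    include <- trial
    meas$excluded[idx_all] <- TRUE
  }

  values <- sol$values
  offset <- NA_real_
  if (anchors$mode %in% c("offset_multi", "bridging")) {
    offset <- anchor_offset(values, anchors$values)
    values <- values + offset
  }
  resid_all <- meas$delta - (values[meas$node_b] - values[meas$node_a])
  meas$residual <- unname(resid_all)
  n_m <- sum(include)
  n_c <- if (nc_counts_anchors) length(values) else
    sol$n_free + as.integer(anchors$mode %in% c("offset_multi", "bridging"))
  SS <- sum(meas$residual[include]^2 * weights[include])
  s <- if (n_m > n_c) sqrt(SS / (n_m - n_c)) else NA_real_
  links <- table(factor(c(meas$node_a[include], meas$node_b[include]),
                        levels = names(values)))
  if (any(links < 2))
    message("note: nodes linked by fewer than two included measurements: ",
            paste(names(links)[links < 2], collapse = ", "))
  structure(list(values = values, measurements = meas, include = include,
                 s = s, SS = SS, n_m = n_m, n_c = n_c,
                 anchors = anchors, offset = offset,
                 links = as.integer(links),
                 nc_counts_anchors = nc_counts_anchors,
                 exclude_threshold = exclude_threshold),
            class = "ladder_fit")
}

#' Consistency standard deviation of a ladder fit
#'
#' \eqn{s = \sqrt{SS/(n_m - n_c)}}; the scale's internal one-sigma scatter.
#' Undefined (returned as \code{NA} with a message) when the degrees of
#' freedom are exhausted.
#'
#' @param fit a \code{\link{fit_ladder}} object.
#' @return numeric scalar, or \code{NA} when \eqn{n_m \le n_c}.
#' @export
consistency_s <- function(fit) {
  stopifnot(inherits(fit, "ladder_fit"))
  if (fit$n_m <= fit$n_c) {
    message("consistency undefined: n_m (", fit$n_m, ") <= n_c (", fit$n_c, ")")
    return(NA_real_)
  }
  sqrt(fit$SS / (fit$n_m - fit$n_c))
}

#' Anchoring offset from external reference values
#'
#' The additive shift minimising the sum of squared differences between the
#' reference values and the relative scale is their mean difference.
#'
#' @param relative_values named numeric: fitted relative scale values.
#' @param calc_anchors named numeric: external reference values (computed pKa
#'   or bridging pH_abs).
#' @return scalar offset to add to every relative value.
#' @export
anchor_offset <- function(relative_values, calc_anchors) {
  common <- intersect(names(relative_values), names(calc_anchors))
  if (length(common) == 0)
    stop("no overlap between scale nodes and anchor reference values")
  mean(calc_anchors[common] - relative_values[common])
}

#' Fit a ladder with iterative exclusion of inconsistent series
#'
#' Convenience wrapper for \code{\link{fit_ladder}} with an exclusion
#' threshold (default 0.75 pH/pK units, the criterion used for the
#' potentiometric ladder).
#'
#' @inheritParams fit_ladder
#' @param threshold absolute-residual exclusion threshold (> 0).
#' @return a \code{\link{fit_ladder}} object with excluded edges flagged.
#' @export
exclude_inconsistent <- function(measurements, anchors, threshold = 0.75, ...) {
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be positive")
  fit_ladder(measurements, anchors, exclude_threshold = threshold, ...)
}

#' Tabular report of a fitted scale
#'
#' Nodes sorted by assigned value, per-edge measured vs. assigned differences,
#' and the scale span (max minus min).
#'
#' @param fit a \code{\link{fit_ladder}} object.
#' @param decreasing sort order of the node table.
#' @return list of class \code{"scale_report"}: \code{nodes} (data frame with
#'   \code{node}, \code{value}, \code{links}, \code{anchor}), \code{edges}
#'   (measured vs assigned delta, residual, exclusion flag), \code{span}.
#' @export
scale_report <- function(fit, decreasing = TRUE) {
  stopifnot(inherits(fit, "ladder_fit"))
  v <- fit$values
  nodes <- data.frame(node = names(v), value = unname(v),
                      links = fit$links,
                      anchor = names(v) %in% names(fit$anchors$values),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$value, decreasing = decreasing), ]
  rownames(nodes) <- NULL
  m <- fit$measurements
  edges <- data.frame(node_a = m$node_a, node_b = m$node_b,
                      measured = m$delta,
                      assigned = unname(v[m$node_b] - v[m$node_a]),
                      residual = m$residual, excluded = m$excluded,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 span = max(v) - min(v), s = fit$s),
            class = "scale_report")
}

#' @export
print.scale_report <- function(x, digits = 1, ...) {
  cat("Scale report:", nrow(x$nodes), "nodes, span",
      format(round_half_up(x$span, digits), nsmall = digits), "\n")
  nd <- x$nodes
  nd$value <- round_half_up(nd$value, digits)
  print(nd, ...)
  if (any(x$edges$excluded))
    cat(sum(x$edges$excluded), "measurement(s) excluded as inconsistent\n")
  invisible(x)
}

#' @export
print.ladder_fit <- function(x, ...) {
  cat("Ladder least-squares fit (", x$anchors$mode, " anchoring)\n", sep = "")
  cat("  nodes:", length(x$values), "  measurements:", x$n_m,
      "included /", nrow(x$measurements), "total\n")
  if (!is.na(x$offset)) cat("  anchoring offset:", format(x$offset), "\n")
  cat("  consistency s:", if (is.na(x$s)) "undefined (n_m <= n_c)" else
    format(signif(x$s, 3)), " (n_m =", x$n_m, ", n_c =", x$n_c, ")\n")
  invisible(x)
}

#' @export
summary.ladder_fit <- function(object, ...) {
  rep <- scale_report(object)
  cat("Assigned scale values (sorted):\n")
  print(rep, ...)
  cat("\nSS =", format(signif(object$SS, 4)),
      " s =", if (is.na(object$s)) "undefined" else format(signif(object$s, 3)), "\n")
  invisible(rep)
}

#' @export
coef.ladder_fit <- function(object, ...) object$values

#' @export
residuals.ladder_fit <- function(object, include_excluded = FALSE, ...) {
  r <- object$measurements$residual
  if (!include_excluded) r <- r[object$include]
  r
}

#' @export
fitted.ladder_fit <- function(object, ...) {
  m <- object$measurements
  unname(object$values[m$node_b] - object$values[m$node_a])
}

#' Predicted pairwise differences from a fitted ladder
#'
#' @param object a \code{\link{fit_ladder}} object.
#' @param newdata data frame with \code{node_a}, \code{node_b}; defaults to
#'   the fitted measurement pairs.
#' @param ... unused.
#' @return numeric vector of assigned-value differences (node_b minus node_a).
#' @export
predict.ladder_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  a <- as.character(newdata$node_a); b <- as.character(newdata$node_b)
  unknown <- setdiff(c(a, b), names(object$values))
  if (length(unknown) > 0)
    stop("nodes not on the fitted scale: ", paste(unique(unknown), collapse = ", "))
  unname(object$values[b] - object$values[a])
}

#' Ladder diagram of a fitted scale
#'
#' Nodes are drawn at their assigned values on a vertical axis; measured
#' differences appear as arrows between rungs (excluded series dashed).
#'
#' @param x a \code{\link{fit_ladder}} object.
#' @param ... passed to \code{plot}.
#' @export
plot.ladder_fit <- function(x, ...) {
  v <- sort(x$values)
  op <- par(mar = c(2, 4, 2, 8)); on.exit(par(op))
  plot(rep(1, length(v)), v, xlim = c(0.5, 3), xlab = "", ylab = "scale value",
       xaxt = "n", pch = 19, ...)
  text(rep(1.08, length(v)), v, names(v), adj = 0, cex = 0.7, xpd = NA)
  m <- x$measurements
  xo <- seq(1.6, 2.9, length.out = max(nrow(m), 2))
  for (i in seq_len(nrow(m))) {
    segments(xo[i], x$values[m$node_a[i]], xo[i], x$values[m$node_b[i]],
             lty = if (m$excluded[i]) 2 else 1,
             col = if (m$excluded[i]) "red" else "grey30")
  }
  invisible(x)
}
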