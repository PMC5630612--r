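#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an RDP set
#'
#' One row per (subject, window) pattern with its cluster assignment.
#'
#' @param x an `rdp_set`.
#' @param ... unused.
#' @return A tibble with `subject`, `window`, `cluster`.
#' @export
tidy.rdp_set <- function(x, ...) {
  n <- length(x$assignments)
  tibble::tibble(
    subject = x$subject %||% rep(NA_character_, n),
    window = x$window %||% rep(NA_integer_, n),
    cluster = x$assignments)
}

#' @rdname tidy.rdp_set
#' @export
glance.rdp_set <- function(x, ...) {
  tibble::tibble(K = x$K, n_patterns = length(x$assignments),
                 objective = x$objective,
                 max_occupancy = max(x$occupancy), seed = x$seed)
}

#' Tidy a consensus curve
#'
#' One row per (fold, K) with the worst-case average held-out distance.
#'
#' @param x a `consensus_curve`.
#' @param ... unused.
#' @return A tibble with `K`, `fold`, `worst_avg_distance`, `selected`.
#' @export
tidy.consensus_curve <- function(x, ...) {
  K <- rep(x$K_values, each = x$folds)
  tibble::tibble(K = K, fold = rep(seq_len(x$folds), length(x$K_values)),
                 worst_avg_distance = as.vector(x$fold_values),
                 selected = K == x$selected_K)
}

#' Tidy a parcellation
#'
#' @param x a `parcellation`.
#' @param ... unused.
#' @return The region table (tibble).
#' @export
tidy.parcellation <- function(x, ...) x$regions

#' @rdname tidy.parcellation
#' @export
glance.parcellation <- function(x, ...) {
  tibble::tibble(n_regions = nrow(x$regions),
                 n_labels = length(unique(x$regions$parent_label)),
                 n_voxels = sum(x$region_id > 0L),
                 connectivity = x$connectivity, min_size = x$min_size)
}

#' Plot a consensus curve
#'
#' Fold-wise worst-case held-out distances per candidate K, with the median
#' line and the selected K highlighted.
#'
#' @param object a `consensus_curve`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.consensus_curve <- function(object, ...) {
  df <- tidy.consensus_curve(object)
  med <- tibble::tibble(K = object$K_values, m = object$medians)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$K, y = .data$worst_avg_distance)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = med, ggplot2::aes(y = .data$m), linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = object$selected_K, linetype = 2) +
    ggplot2::labs(x = "number of RDPs (K)",
                  y = "worst-case average held-out distance (1 - |cos|)",
                  title = sprintf("Consensus selection: K = %d", object$selected_K))
}

#' Plot RDP occupancy
#'
#' @param object an `rdp_set`.
#' @param ... unused.
#' @return A ggplot object of occupancy fractions per RDP.
#' @export
autoplot.rdp_set <- function(object, ...) {
  df <- tibble::tibble(RDP = factor(seq_len(object$K)),
                       occupancy = object$occupancy)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$RDP, y = .data$occupancy)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(y = "fraction of windows", title = "RDP temporal occupancy")
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
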