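#' Plot methods
#'
#' `autoplot()` methods give quick diagnostic graphics: trace and density
#' panels for Gibbs chains, the likelihood trace for REML fits, EBV
#' distributions per genetic effect, and score distributions for records.
#'
#' @param object The object to plot.
#' @param parameters For chains: which sampled/derived parameters to show
#'   (default: the genetic components).
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-beeval
NULL

#' @rdname autoplot-beeval
#' @method autoplot beeval_chain
#' @export
autoplot.beeval_chain <- function(object, parameters = NULL, ...) {
  s <- derive_chain_params(object)
  parameters <- parameters %||%
    grep("^(sigma2_|cov_)", names(object$samples), value = TRUE)
  s$iteration <- seq_len(nrow(s))
  long <- tidyr::pivot_longer(s[, c("iteration", parameters)],
                              -"iteration", names_to = "parameter")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2, colour = "steelblue") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "retained iteration", y = NULL,
                  title = "Gibbs chain traces") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-beeval
#' @method autoplot beeval_reml
#' @export
autoplot.beeval_reml <- function(object, ...) {
  df <- tibble(iteration = seq_along(object$logLik) - 1L,
               logLik = object$logLik)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$logLik)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "iteration", y = "restricted log-likelihood",
                  title = "AI-REML convergence") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-beeval
#' @method autoplot beeval_blup
#' @export
autoplot.beeval_blup <- function(object, ...) {
  ggplot2::ggplot(object$ebv, ggplot2::aes(x = .data$ebv)) +
    ggplot2::geom_histogram(bins = 40, fill = "goldenrod", colour = "grey30") +
    ggplot2::facet_wrap(~effect, scales = "free") +
    ggplot2::labs(x = "estimated breeding value", y = "individuals",
                  title = sprintf("EBV distribution (%s)", object$trait)) +
    ggplot2::theme_minimal()
}

#' Behaviour score distribution
#'
#' Bar chart of the 5-category defensive and swarming scores (the
#' registry scores are strongly right-skewed: most colonies are gentle
#' and reluctant to swarm).
#'
#' @param records Records tibble.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(records) {
  long <- tidyr::pivot_longer(records[, c("defensive", "swarming")],
                              dplyr::everything(),
                              names_to = "trait", values_to = "score")
  long <- long[!is.na(long$score), ]
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$score, levels = 1:5))) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::facet_wrap(~trait) +
    ggplot2::labs(x = "score", y = "colonies") +
    ggplot2::theme_minimal()
}
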