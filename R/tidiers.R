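# broom-style tidy()/glance() methods and ggplot2 autoplot() methods for
# every result type, so results drop straight into dplyr/ggplot2 pipelines.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy per-sample taxonomic index values
#' @param x A `taxondive_result`.
#' @param ... Unused.
#' @return Tibble with one row per sample.
#' @method tidy taxondive_result
#' @export
tidy.taxondive_result <- function(x, ...) x$samples

#' One-row summary of a taxonomic index run
#' @param x A `taxondive_result`.
#' @param ... Unused.
#' @method glance taxondive_result
#' @export
glance.taxondive_result <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$samples),
    S_pool = x$S,
    EDeltaPlus = x$EDeltaPlus,
    n_blocks = x$accounting$n_blocks %||% NA_integer_,
    block_rows = x$accounting$block_rows %||% NA_integer_
  )
}

#' @method tidy eco_anosim
#' @export
tidy.eco_anosim <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, nperm = x$perm$nperm,
                 exceed = as.double(x$perm$exceed),
                 p.value = x$perm$p_value)
}

#' @method glance eco_anosim
#' @export
glance.eco_anosim <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$perm$p_value,
                 nperm = x$perm$nperm, n = x$n,
                 n_groups = length(x$group_sizes))
}

#' @method tidy eco_permanova
#' @export
tidy.eco_permanova <- function(x, ...) {
  tab <- x$table
  tab$p.value <- c(x$perm$p_value, NA_real_, NA_real_)
  tab
}

#' @method glance eco_permanova
#' @export
glance.eco_permanova <- function(x, ...) {
  tibble::tibble(pseudo_F = x$statistic,
                 R2 = x$table$R2[1],
                 p.value = x$perm$p_value,
                 nperm = x$perm$nperm, n = x$n)
}

#' @method tidy eco_simper
#' @export
tidy.eco_simper <- function(x, ...) {
  dplyr::bind_rows(
    lapply(names(x$tables), function(nm) {
      dplyr::mutate(x$tables[[nm]], contrast = nm, .before = 1)
    })
  )
}

#' @method glance eco_simper
#' @export
glance.eco_simper <- function(x, ...) {
  tibble::tibble(contrast = names(x$overall),
                 overall_dissimilarity = as.double(x$overall),
                 nperm = x$perm$nperm)
}

#' @method tidy eco_mantel
#' @export
tidy.eco_mantel <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, method = x$method,
                 partial = x$partial, nperm = x$perm$nperm,
                 p.value = x$perm$p_value)
}

#' @method glance eco_mantel
#' @export
glance.eco_mantel <- function(x, ...) tidy.eco_mantel(x, ...)

#' @method tidy eco_bioenv
#' @export
tidy.eco_bioenv <- function(x, ...) x$by_size

#' @method glance eco_bioenv
#' @export
glance.eco_bioenv <- function(x, ...) {
  tibble::tibble(best_variables = x$best$variables,
                 best_size = x$best$size, best_rho = x$best$rho,
                 n_evaluated = x$n_evaluated, n_vars = x$n_vars)
}

#' Funnel plot of expected Delta+ against subsample richness
#'
#' @param object A `funnel_table` from [funnel()].
#' @param observed Optional tibble of observed samples with columns
#'   `richness` and `DeltaPlus` (e.g. `tidy()` of a `taxondive_result`)
#'   overlaid as points.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot funnel_table
#' @export
autoplot.funnel_table <- function(object, observed = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$m)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::geom_hline(yintercept = attr(object, "EDeltaPlus"),
                        linetype = "dashed") +
    ggplot2::labs(x = "subsample species richness",
                  y = expression(Delta^"+"),
                  title = "Taxonomic distinctness funnel")
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_point(
      data = observed,
      ggplot2::aes(x = .data$richness, y = .data$DeltaPlus))
  }
  p
}

#' Bar chart of the top SIMPER contributions
#'
#' @param object An `eco_simper`.
#' @param top Number of species shown per contrast.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eco_simper
#' @export
autoplot.eco_simper <- function(object, top = 10, ...) {
  df <- tidy(object) |>
    dplyr::group_by(.data$contrast) |>
    dplyr::slice_head(n = top) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$species, .data$average),
                                   y = .data$average)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~contrast, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean contribution to dissimilarity")
}

#' BioEnv correlation by subset size
#'
#' @param object An `eco_bioenv`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eco_bioenv
#' @export
autoplot.eco_bioenv <- function(object, ...) {
  ggplot2::ggplot(object$by_size,
                  ggplot2::aes(x = .data$size, y = .data$rho)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "subset size", y = "Spearman rho",
                  title = "Best environmental subset by size")
}
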