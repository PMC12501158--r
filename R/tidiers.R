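#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @method tidy tn_pca
#' @export
tidy.tn_pca <- function(x, ...) {
  tidyr::pivot_longer(x$scores, -"sample",
                      names_to = "component", values_to = "score")
}

#' @method glance tn_pca
#' @export
glance.tn_pca <- function(x, ...) {
  tibble(n_samples = nrow(x$scores),
         n_components = x$n_components,
         variance_explained = sum(x$explained_variance))
}

#' @method tidy bottleneck_fit
#' @export
tidy.bottleneck_fit <- function(x, ...) {
  tibble(survival_lower = x$survival_lower,
         survival_upper = x$survival_upper,
         consumed_lower_pct = (1 - x$survival_upper) * 100,
         consumed_upper_pct = (1 - x$survival_lower) * 100,
         open = x$open,
         observed_loss = x$observed_loss)
}

#' @method glance bottleneck_fit
#' @export
glance.bottleneck_fit <- function(x, ...) {
  tibble(n_grid = nrow(x$grid_summary),
         observed_loss = x$observed_loss,
         report = consumed_fraction_report(x))
}
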