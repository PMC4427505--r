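#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted linear model
#'
#' @param x a `ddi_model`.
#' @param ... unused.
#' @return a tibble with one row per feature: `feature`, `weight`, plus the
#'   bias as the `(bias)` pseudo-feature row at the end.
#' @method tidy ddi_model
#' @export
tidy.ddi_model <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(feature = names(x$weights) %||%
                     paste0("f", seq_along(x$weights)),
                   weight = unname(x$weights)),
    tibble::tibble(feature = "(bias)", weight = x$bias)
  )
}

#' @rdname tidy.ddi_model
#' @method glance ddi_model
#' @export
glance.ddi_model <- function(x, ...) {
  hp <- x$hyperparameters
  tibble::tibble(
    classifier = x$classifier,
    n_features = length(x$weights),
    bias = x$bias,
    hyperparameters = paste(names(hp), unlist(lapply(hp, function(v)
      paste(format(unlist(v)), collapse = ","))), sep = "=", collapse = "; ")
  )
}

#' Tidy a cross-validation report
#'
#' @param x a `ddi_eval` from [evaluate_configuration()].
#' @param ... unused.
#' @return `tidy()`: per-fold metrics in long form (`repeat_ix`, `fold_ix`,
#'   `metric`, `value`). `glance()`: one row of across-fold means.
#' @method tidy ddi_eval
#' @export
tidy.ddi_eval <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(c("f1", "mcc", "iauc"),
                        names_to = "metric", values_to = "value") |>
    dplyr::select("repeat_ix", "fold_ix", "metric", "value")
}

#' @rdname tidy.ddi_eval
#' @method glance ddi_eval
#' @export
glance.ddi_eval <- function(x, ...) {
  tibble::tibble(
    configuration = attr(x, "config")$label,
    f1 = mean(x$f1), mcc = mean(x$mcc), iauc = mean(x$iauc),
    n_folds = nrow(x), plan_seed = attr(x, "plan_seed")
  )
}

#' @export
print.ddi_eval <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<ddi_eval %s: %d folds; mean F1 %.3f, MCC %.3f, iAUC %.3f>\n",
              g$configuration, g$n_folds, g$f1, g$mcc, g$iauc))
  NextMethod()
}
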