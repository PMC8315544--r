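#' Certainty-versus-gamble decision surface
#'
#' For a fixed choice between a certain amount and a two-outcome gamble,
#' computes the CPT value difference
#' `V_certainty(b) - V_gamble(b, alpha)` over a grid of reference points
#' and Prelec parameters. A positive cell means the agent prefers the
#' certainty at that `(b, alpha)`; the zero contour is the decision
#' boundary.
#'
#' @param r_certain Certain outcome.
#' @param r_plus,r_minus Gamble outcomes (`r_plus > r_minus`).
#' @param p Probability of `r_plus`.
#' @param b_grid Numeric grid of reference points.
#' @param alpha_grid Numeric grid of Prelec parameters.
#' @param utility A [utility_spec()] (default: the power utility with
#'   `gamma = 0.85`, `lambda = 2`).
#' @param delta Prelec exponent held fixed across the grid.
#' @return A tibble with columns `b`, `alpha`, `certainty`, `gamble`,
#'   `difference`; class `cpt_surface`.
#' @examples
#' decision_surface(900, 1000, 0, 0.95, b_grid = c(-100, 0, 100),
#'                  alpha_grid = c(0.5, 1, 2))
#' @export
decision_surface <- function(r_certain, r_plus, r_minus, p,
                             b_grid, alpha_grid,
                             utility = utility_spec("power", gamma = 0.85,
                                                    lambda = 2),
                             delta = 0.75) {
  stopifnot(length(b_grid) >= 1L, length(alpha_grid) >= 1L,
            r_plus > r_minus)
  grid <- tidyr::expand_grid(b = b_grid, alpha = alpha_grid)
  vals <- purrr::map2(grid$b, grid$alpha, function(b, a) {
    params <- cpt_params(utility,
                         weighting_spec("prelec", alpha = a, delta = delta),
                         reference_point = b)
    cert <- certainty_value(r_certain, params)
    gam <- gamble_value(r_plus, r_minus, p, params)
    tibble::tibble(certainty = cert, gamble = gam, difference = cert - gam)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(vals))
  class(out) <- c("cpt_surface", class(out))
  out
}

#' @export
autoplot.cpt_surface <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$alpha, y = .data$b,
                                       fill = .data$difference)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue", midpoint = 0) +
    ggplot2::labs(x = "Prelec parameter α", y = "reference point b",
                  fill = "V(certainty)\n- V(gamble)") +
    ggplot2::theme_minimal()
}

#' Write a surface tibble as a tab-separated matrix
#'
#' Reshapes a `(b, alpha, value)` surface into a matrix with reference
#' points as rows and grid values as headers, and writes it as TSV.
#'
#' @param surface A tibble with two grid columns and a value column.
#' @param path Output file path.
#' @param rows,cols,value Column names for rows, columns, and cells.
#' @return `path`, invisibly.
#' @export
write_surface_tsv <- function(surface, path, rows = "b", cols = "alpha",
                              value = "difference") {
  wide <- tidyr::pivot_wider(
    surface[, c(rows, cols, value)],
    names_from = dplyr::all_of(cols),
    values_from = dplyr::all_of(value))
  utils::write.table(wide, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
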