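#' Idealised 64-channel 10/20 montage
#'
#' Returns the electrode layout used throughout the package: the extended
#' 10/20 (10-10) label set on an idealised head, with 2-D positions in the
#' usual top-view projection (vertex Cz at the origin, nose up, unit radius
#' at the lowest standard ring; Iz and P9/P10 fall slightly outside it).
#' Positions are schematic — they carry relative scalp distances for the
#' response topography, neighbour interpolation and plotting, not digitised
#' sensor coordinates.
#'
#' @param labels Optional character vector restricting (and ordering) the
#'   montage to a subset of labels.
#' @return A tibble with columns `electrode`, `x`, `y` in montage order.
#' @examples
#' head(montage_1020())
#' montage_1020(c("Oz", "POz", "Iz"))
#' @export
montage_1020 <- function(labels = NULL) {
  m <- montage_table()
  if (!is.null(labels)) {
    missing <- setdiff(labels, m$electrode)
    if (length(missing) > 0) {
      stop("unknown electrode label(s): ", paste(missing, collapse = ", "))
    }
    m <- m[match(labels, m$electrode), ]
  }
  tibble::as_tibble(m)
}

# grid construction: anterior-posterior rows (Fp..O, plus Iz/P9/P10 below the
# ring) crossed with lateral columns 7,5,3,1,z,2,4,6,8; x = lateral/4,
# y = row/4.  Only relative distances matter downstream.
montage_table <- function() {
  rows <- list(
    Fp = list(a = 4,  cols = c(1, 0, 2)),                # Fp1 Fpz Fp2
    AF = list(a = 3,  cols = c(-4, -2, 0, 2, 4)),        # AF7 AF3 AFz AF4 AF8
    F  = list(a = 2,  cols = c(-4, -3, -2, -1, 0, 1, 2, 3, 4)),
    FC = list(a = 1,  cols = c(-4, -3, -2, -1, 0, 1, 2, 3, 4)),
    C  = list(a = 0,  cols = c(-4, -3, -2, -1, 0, 1, 2, 3, 4)),
    CP = list(a = -1, cols = c(-4, -3, -2, -1, 0, 1, 2, 3, 4)),
    P  = list(a = -2, cols = c(-4, -3, -2, -1, 0, 1, 2, 3, 4)),
    PO = list(a = -3, cols = c(-4, -2, 0, 2, 4)),        # PO7 PO3 POz PO4 PO8
    O  = list(a = -4, cols = c(-1, 0, 1))                # O1 Oz O2
  )
  lab_for <- function(prefix, col) {
    if (col == 0) return(paste0(prefix, "z"))
    idx <- abs(col) * 2 - (col < 0)           # -1 -> 1, 1 -> 2, -2 -> 3, ...
    paste0(prefix, idx)
  }
  out <- list()
  for (prefix in names(rows)) {
    r <- rows[[prefix]]
    for (col in r$cols) {
      lab <- lab_for(prefix, col)
      # lateral rows use the anatomical names at the ends
      if (prefix == "F" && col == -4) lab <- "F7"
      if (prefix == "F" && col == 4) lab <- "F8"
      if (prefix == "FC" && col == -4) lab <- "FT7"
      if (prefix == "FC" && col == 4) lab <- "FT8"
      if (prefix == "C" && col == -4) lab <- "T7"
      if (prefix == "C" && col == 4) lab <- "T8"
      if (prefix == "CP" && col == -4) lab <- "TP7"
      if (prefix == "CP" && col == 4) lab <- "TP8"
      if (prefix == "P" && col == -4) lab <- "P7"
      if (prefix == "P" && col == 4) lab <- "P8"
      if (prefix == "Fp") lab <- c("Fp1", "Fpz", "Fp2")[match(col, c(1, 0, 2))]
      out[[length(out) + 1L]] <- data.frame(
        electrode = lab, x = col / 4, y = r$a / 4, stringsAsFactors = FALSE
      )
    }
  }
  # Fp1/Fp2 sit just lateral of Fpz on the front ring
  out <- do.call(rbind, out)
  out$x[out$electrode == "Fp1"] <- -0.25
  out$y[out$electrode == "Fp1"] <- 0.97
  out$x[out$electrode == "Fp2"] <- 0.25
  out$y[out$electrode == "Fp2"] <- 0.97
  out$x[out$electrode == "O1"] <- -0.25
  out$y[out$electrode == "O1"] <- -0.97
  out$x[out$electrode == "O2"] <- 0.25
  out$y[out$electrode == "O2"] <- -0.97
  below <- data.frame(
    electrode = c("Iz", "P9", "P10"),
    x = c(0, -1.12, 1.12),
    y = c(-1.25, -0.62, -0.62),
    stringsAsFactors = FALSE
  )
  rbind(out, below)
}

#' Scalp distance of every montage electrode from a reference electrode
#'
#' @param montage Montage tibble as returned by [montage_1020()].
#' @param from Electrode label distances are measured from (default `"Oz"`).
#' @return Named numeric vector of Euclidean distances in layout units.
#' @keywords internal
montage_distances <- function(montage, from = "Oz") {
  i <- match(from, montage$electrode)
  if (is.na(i)) stop("electrode not in montage: ", from)
  d <- sqrt((montage$x - montage$x[i])^2 + (montage$y - montage$y[i])^2)
  stats::setNames(d, montage$electrode)
}

#' Default occipital reference set
#'
#' The five occipital electrodes used for local re-referencing.
#' @return Character vector of electrode labels.
#' @export
occipital_set <- function() c("O1", "O2", "Oz", "POz", "Iz")
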