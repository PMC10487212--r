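#' Generate a commercial-availability table for optical components
#'
#' The table lists, for every wavelength on the 5 nm grid from 420 to
#' 1600 nm (237 rows), whether a bandpass optical filter, an LED, or a
#' laser is commercially available at that wavelength. `"dense"` marks
#' everything available; `"sparse"` draws random availability patterns that
#' mimic real catalogues (filters widely available, LEDs common in the
#' visible, lasers at scattered lines).
#'
#' @param spec `"dense"` or `"sparse"`.
#' @param seed integer seed (used by `"sparse"`).
#' @param p_filter,p_led,p_laser sparse-mode availability probabilities.
#' @return data.frame `wavelength, available_filter, available_led,
#'   available_laser` with class `availability_table`.
#' @export
generate_availability_table <- function(spec = c("dense", "sparse"),
                                        seed = 1L,
                                        p_filter = 0.8, p_led = 0.5,
                                        p_laser = 0.15) {
  spec <- match.arg(spec)
  wl <- seq(420, 1600, by = 5)
  n <- length(wl)
  if (spec == "dense") {
    tab <- data.frame(wavelength = wl,
                      available_filter = TRUE,
                      available_led = TRUE,
                      available_laser = TRUE)
  } else {
    tab <- with_seed(seed, {
      led_p <- ifelse(wl <= 1000, p_led * 1.5, p_led * 0.5)
      data.frame(
        wavelength = wl,
        available_filter = stats::runif(n) < p_filter,
        available_led = stats::runif(n) < pmin(led_p, 0.95),
        available_laser = stats::runif(n) < p_laser
      )
    })
    for (col in c("available_filter", "available_led", "available_laser")) {
      if (!any(tab[[col]])) tab[[col]][which.min(abs(wl - 500))] <- TRUE
    }
  }
  class(tab) <- c("availability_table", "data.frame")
  tab
}

#' Read / write availability tables as CSV
#'
#' @param path file path.
#' @return `read_availability_table` returns a validated
#'   `availability_table`.
#' @export
read_availability_table <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("wavelength", "available_filter", "available_led",
            "available_laser")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("availability table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in need[-1]) {
    v <- tab[[col]]
    if (is.character(v)) {
      u <- toupper(trimws(v))
      v <- ifelse(u %in% c("TRUE", "1", "T"), TRUE,
                  ifelse(u %in% c("FALSE", "0", "F"), FALSE, NA))
    }
    if (!is.logical(v)) v <- as.logical(v)
    bad <- which(is.na(v))
    if (length(bad)) {
      stop("malformed ", col, " at line(s) ",
           paste(bad + 1, collapse = ", "))
    }
    tab[[col]] <- v
  }
  wl_num <- suppressWarnings(as.numeric(tab$wavelength))
  bad <- which(is.na(wl_num))
  if (length(bad)) {
    stop("malformed wavelength at line(s) ", paste(bad + 1, collapse = ", "))
  }
  tab$wavelength <- wl_num
  if (any(diff(tab$wavelength) <= 0)) {
    stop("wavelength grid must be strictly increasing")
  }
  class(tab) <- c("availability_table", "data.frame")
  tab
}

#' @rdname read_availability_table
#' @param tab an availability table.
#' @export
write_availability_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab)[c("wavelength", "available_filter",
                                        "available_led", "available_laser")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a wavelength grid to commercially available candidates
#'
#' `modality = "filter"` keeps wavelengths with an available bandpass
#' filter; `modality = "light_source"` keeps wavelengths where an LED *or*
#' a laser is available.
#'
#' @param wavelengths nm vector (e.g. the fused spectrum grid).
#' @param availability an `availability_table`.
#' @param modality `"filter"` or `"light_source"`.
#' @return The available subset of `wavelengths` (same order).
#' @export
filter_available <- function(wavelengths, availability,
                             modality = c("filter", "light_source")) {
  modality <- match.arg(modality)
  flag <- if (modality == "filter") {
    availability$available_filter
  } else {
    availability$available_led | availability$available_laser
  }
  ok_wl <- availability$wavelength[flag]
  out <- wavelengths[wavelengths %in% ok_wl]
  if (!length(out)) {
    stop("no ", modality, "-available wavelengths on this grid")
  }
  out
}
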