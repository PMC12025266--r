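#' Load metabolite integration windows
#'
#' Reads a chemical-shift window table with columns
#' `Metabolism,Center,From,To` (the packaged default mirrors the published
#' brain-metabolite ranges; several rows list From > To and are reordered on
#' load). Windows are returned with `lo < hi` regardless of printed order.
#'
#' @param source A CSV path or a data.frame with the four columns. Defaults to
#'   the packaged window table.
#' @return A data.frame with columns `name`, `center`, `lo`, `hi`, one row per
#'   metabolite, with a warning listing any overlapping window pairs.
#' @export
load_windows <- function(source = default_windows_path()) {
  tab <- if (is.data.frame(source)) source else utils::read.csv(source, check.names = FALSE)
  need <- c("Metabolism", "Center", "From", "To")
  if (!all(need %in% names(tab))) {
    # accept the internal lowercase dialect too
    alt <- c("name", "center", "from", "to")
    if (all(alt %in% names(tab))) {
      tab <- data.frame(Metabolism = tab$name, Center = tab$center,
                        From = tab$from, To = tab$to)
    } else {
      stop("window table must have columns Metabolism, Center, From, To",
           call. = FALSE)
    }
  }
  if (anyDuplicated(tab$Metabolism))
    stop("duplicate metabolite name(s) in window table: ",
         paste(unique(tab$Metabolism[duplicated(tab$Metabolism)]), collapse = ", "),
         call. = FALSE)
  w <- data.frame(
    name = as.character(tab$Metabolism),
    center = as.numeric(tab$Center),
    lo = pmin(as.numeric(tab$From), as.numeric(tab$To)),
    hi = pmax(as.numeric(tab$From), as.numeric(tab$To)),
    stringsAsFactors = FALSE
  )
  bad <- which(w$center < w$lo | w$center > w$hi)
  if (length(bad))
    stop("window center outside [lo, hi] for row(s): ",
         paste(w$name[bad], collapse = ", "), call. = FALSE)
  ov <- character(0)
  if (nrow(w) > 1) {
    for (i in seq_len(nrow(w) - 1)) for (j in seq(i + 1, nrow(w))) {
      if (w$lo[i] < w$hi[j] && w$lo[j] < w$hi[i])
        ov <- c(ov, paste0(w$name[i], "/", w$name[j]))
    }
  }
  if (length(ov))
    warning("overlapping integration windows: ", paste(ov, collapse = ", "),
            call. = FALSE)
  w
}

#' @rdname load_windows
#' @export
default_windows_path <- function() {
  system.file("extdata", "metabolite_windows.csv", package = "pocenmr",
              mustWork = TRUE)
}

#' @rdname load_windows
#' @export
default_windows <- function() load_windows(default_windows_path())

window_for <- function(windows, name) {
  i <- match(name, windows$name)
  if (is.na(i)) stop("no integration window defined for metabolite: ", name,
                     call. = FALSE)
  windows[i, , drop = FALSE]
}
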