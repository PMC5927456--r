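# Internal helpers shared across modules.

# Consistent error for bad user input.
stop_input <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "plastinorm_input_error")
}

# Degenerate-but-well-formed input (e.g. zero variance, empty layer).
stop_degenerate <- function(msg, ...) {
  abort(sprintf(msg, ...), class = c("plastinorm_degenerate_error",
                                     "plastinorm_input_error"))
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_input("%s is missing required column(s): %s", what,
               paste(missing, collapse = ", "))
  }
  invisible(df)
}

# Month key ("YYYY-MM") from Date or character input.
month_key <- function(x) {
  if (inherits(x, "Date")) return(format(x, "%Y-%m"))
  x <- as.character(x)
  ifelse(grepl("^\\d{4}-\\d{2}$", x), x,
         format(as.Date(x), "%Y-%m"))
}

# Sample SD that returns NA (not an error) for n = 1.
sd_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  sd(x)
}
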