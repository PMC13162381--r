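## Small shared helpers. None exported.

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

round_to <- function(x, unit) round(x / unit) * unit

## Format a number for prose: fixed decimals, trailing zeros stripped
## ("12.50" -> "12.5", "87.0" -> "87", "29.1" stays "29.1").
fmt_num <- function(x, digits = 2) {
  s <- sprintf(paste0("%.", digits, "f"), x)
  has_dot <- grepl("\\.", s)
  s[has_dot] <- sub("\\.?0+$", "", s[has_dot])
  s
}

## Deterministic child seeds so pipeline stages can be rerun independently
## without perturbing each other's draws. Kept under 2^31 - 1.
child_seed <- function(root, k) {
  as.integer((as.numeric(root) + 1000003 * k) %% 2147483647)
}

## Expand a scalar or partially named vector to a full named nutrient vector.
nutrient_param <- function(x, default, what) {
  out <- setNames(rep(default, length(NUTRIENTS)), NUTRIENTS)
  if (is.null(x)) return(out)
  if (is.null(names(x))) {
    if (length(x) == 1) {
      out[] <- x
    } else if (length(x) == length(NUTRIENTS)) {
      out[] <- x
    } else {
      stop(what, " must be a scalar, a named vector, or length 7",
           call. = FALSE)
    }
    return(out)
  }
  bad <- setdiff(names(x), NUTRIENTS)
  if (length(bad) > 0) {
    stop("unknown nutrient(s) in ", what, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out[names(x)] <- x
  out
}

check_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(what, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}
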