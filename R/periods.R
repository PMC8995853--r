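# Broad archaeological periods, years before 1950 (BP). Intervals are closed
# at the older bound and open at the younger bound, [young_bp, old_bp), so
# every positive age maps to at least one period. Age 0 is Modern by
# definition. Two deliberate overlaps exist in the printed boundaries:
# Mesolithic/Neolithic share [5500, 8500) and Neolithic/PostNeolithic share
# [3900, 5000); samples dated into an overlap need an explicit label.
period_table <- function() {
  data.frame(
    period   = c("EUP", "LUP", "Mesolithic", "Neolithic", "PostNeolithic"),
    old_bp   = c(Inf, 25000, 11000, 8500, 5000),
    young_bp = c(25000, 11000, 5500, 3900, 0),
    stringsAsFactors = FALSE
  )
}

#' Canonical period labels, oldest first
#'
#' @return Character vector of the six period labels in chronological order:
#'   Early Upper Paleolithic (EUP), Late Upper Paleolithic (LUP), Mesolithic,
#'   Neolithic, PostNeolithic, Modern.
#' @export
period_levels <- function() {
  c("EUP", "LUP", "Mesolithic", "Neolithic", "PostNeolithic", "Modern")
}

#' Assign a broad archaeological period from a carbon-dated age
#'
#' Maps ages (years before 1950) onto the period boundaries: EUP at 25,000 BP
#' and older, LUP \[11,000, 25,000), Mesolithic \[5,500, 11,000), Neolithic
#' \[3,900, 8,500), PostNeolithic below 5,000, and Modern at exactly age 0.
#' The Mesolithic/Neolithic and Neolithic/PostNeolithic boundaries overlap;
#' an age falling in an overlap zone is resolved by `explicit_label` (the
#' role archaeological context plays for real samples) and is an error when
#' no label is supplied.
#'
#' @param age_bp Numeric vector of ages in years before 1950; must be >= 0.
#' @param explicit_label Optional character vector (recycled if length 1) of
#'   period labels used to resolve ages in overlap zones.
#' @return Character vector of period labels.
#' @export
assign_period <- function(age_bp, explicit_label = NULL) {
  if (any(is.na(age_bp))) stop("age_bp must not be NA", call. = FALSE)
  if (any(age_bp < 0)) stop("age_bp must be non-negative", call. = FALSE)
  if (!is.null(explicit_label)) {
    explicit_label <- rep_len(as.character(explicit_label), length(age_bp))
  }
  tab <- period_table()
  out <- character(length(age_bp))
  for (i in seq_along(age_bp)) {
    age <- age_bp[i]
    if (age == 0) {
      out[i] <- "Modern"
      next
    }
    hit <- tab$period[age >= tab$young_bp & age < tab$old_bp]
    if (length(hit) == 1L) {
      out[i] <- hit
    } else {
      lab <- if (is.null(explicit_label)) NA_character_ else explicit_label[i]
      if (!is.na(lab) && lab %in% hit) {
        out[i] <- lab
      } else if (!is.na(lab)) {
        stop("explicit period label '", lab, "' for age ", age,
             " is not among the candidate periods {",
             paste(hit, collapse = ", "), "}", call. = FALSE)
      } else {
        stop("ambiguous period for age ", age, ": candidates {",
             paste(hit, collapse = ", "),
             "}; an explicit label is required in overlap zones",
             call. = FALSE)
      }
    }
  }
  out
}

# Resolve a (possibly pooled) period-group label to its member periods.
# "PreNeolithic" pools EUP, LUP and Mesolithic; "PostBreakpoint" pools
# Neolithic, PostNeolithic and Modern.
resolve_period_group <- function(label) {
  groups <- list(
    PreNeolithic   = c("EUP", "LUP", "Mesolithic"),
    PostBreakpoint = c("Neolithic", "PostNeolithic", "Modern")
  )
  if (label %in% names(groups)) return(groups[[label]])
  if (label %in% period_levels()) return(label)
  stop("unknown period or period group: ", label, call. = FALSE)
}
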