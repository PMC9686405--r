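#' Scale and spectrum layout
#'
#' The nine restructured-clinical-style scales covered by the generator and
#' pipeline, the six HiTOP-style spectra, and the default assignment of
#' scales to spectra (internalizing: RCd, RC7; detachment: RC2; somatoform:
#' RC1; thought disorder: RC6, RC8; disinhibited externalizing: RC4;
#' antagonistic externalizing: RC9, RC3). RC3 carries a secondary
#' association with the thought-disorder spectrum.
#'
#' @return `rc_scales()` returns the scale names in canonical order;
#'   `spectrum_names()` the six spectrum labels; `default_spectra_map()` a
#'   `spectra_map` object: a list with `primary` (named character vector,
#'   scale -> spectrum) and `secondary` (named character vector of optional
#'   secondary spectrum assignments).
#' @examples
#' default_spectra_map()$primary[["RC4"]]
#' @export
rc_scales <- function() {
  c("RCd", "RC1", "RC2", "RC3", "RC4", "RC6", "RC7", "RC8", "RC9")
}

#' @rdname rc_scales
#' @export
spectrum_names <- function() {
  c("internalizing", "detachment", "somatoform", "thought_disorder",
    "disinhibited_externalizing", "antagonistic_externalizing")
}

#' @rdname rc_scales
#' @export
default_spectra_map <- function() {
  primary <- c(
    RCd = "internalizing",
    RC1 = "somatoform",
    RC2 = "detachment",
    RC3 = "antagonistic_externalizing",
    RC4 = "disinhibited_externalizing",
    RC6 = "thought_disorder",
    RC7 = "internalizing",
    RC8 = "thought_disorder",
    RC9 = "antagonistic_externalizing"
  )
  structure(list(primary = primary,
                 secondary = c(RC3 = "thought_disorder")),
            class = "spectra_map")
}

#' @export
print.spectra_map <- function(x, ...) {
  cat("Scale -> spectrum assignment (6 spectra):\n")
  for (sp in unique(x$primary)) {
    cat(sprintf("  %-27s %s\n", sp,
                paste(names(x$primary)[x$primary == sp], collapse = ", ")))
  }
  if (length(x$secondary)) {
    cat("Secondary assignments:\n")
    for (i in seq_along(x$secondary)) {
      cat(sprintf("  %s -> %s\n", names(x$secondary)[i], x$secondary[i]))
    }
  }
  invisible(x)
}

#' Spectra shared by two scales
#'
#' @param map a `spectra_map`
#' @param a,b scale names
#' @return `TRUE` if `a` and `b` share a primary or secondary spectrum.
#' @keywords internal
shares_spectrum <- function(map, a, b) {
  sa <- c(map$primary[[a]], unname(map$secondary[names(map$secondary) == a]))
  sb <- c(map$primary[[b]], unname(map$secondary[names(map$secondary) == b]))
  length(intersect(sa, sb)) > 0
}

#' Default higher-order composite map
#'
#' Which scales' content the three higher-order scores summarise:
#' EID (emotional/internalizing dysfunction), THD (thought dysfunction) and
#' BXD (behavioral/externalizing dysfunction).
#'
#' @return named list of character vectors of scale names.
#' @export
default_higher_order_map <- function() {
  list(EID = c("RCd", "RC2", "RC7"),
       THD = c("RC6", "RC8"),
       BXD = c("RC4", "RC9"))
}

#' Which spectra each higher-order variable measures (generator side)
#' @keywords internal
ho_spectra_map <- function() {
  list(EID = c("internalizing", "detachment"),
       THD = "thought_disorder",
       BXD = c("disinhibited_externalizing", "antagonistic_externalizing"))
}

#' Infer variable roles from column names
#'
#' Reserved names: `sample`, `age`, `gender` get role `context`; variables
#' starting with `p_factor` get role `proxy`; `EID`, `THD`, `BXD` get role
#' `higher_order`; everything else is `system`.
#'
#' @param vars character vector of variable names
#' @return named character vector of roles.
#' @export
infer_roles <- function(vars) {
  roles <- rep("system", length(vars))
  names(roles) <- vars
  roles[vars %in% c("sample", "age", "gender")] <- "context"
  roles[startsWith(vars, "p_factor")] <- "proxy"
  roles[vars %in% c("EID", "THD", "BXD")] <- "higher_order"
  roles
}
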