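#' Genotype parameters for the segregation simulator
#'
#' Encodes the categorical rules by which a genotype shapes meiosis I/II
#' chromosome segregation: whether sister kinetochores mono-orient in meiosis
#' I, whether pericentromeric cohesin is protected through anaphase I,
#' whether separase cleavage is competent, and whether a second meiotic
#' division takes place.
#'
#' @param name Genotype label.
#' @param p_monoorient Probability in `[0, 1]` that the sister kinetochores of
#'   a chromosome co-orient to the same spindle pole in meiosis I. Wild type
#'   is 1; loss of Spo13 abolishes mono-orientation (0), leaving each sister
#'   to attach independently and uniformly at random to one of the two poles.
#' @param protection_on Is pericentromeric cohesin protected in anaphase I
#'   (shugoshin/PP2A pathway intact)?
#' @param cleavage_on Is separase cleavage competent? `FALSE` for
#'   temperature-sensitive separase (esp1-2) or non-cleavable Rec8
#'   conditions.
#' @param second_division_on Does meiosis II occur? Cells lacking Spo13
#'   execute a single division; deleting MAD2 restores the second division.
#' @param p_missegregate_mii Probability in `[0, 1]` that a sister pair
#'   missegregates (co-segregates) in meiosis II.
#' @param forced_biorientation If `TRUE`, sister kinetochores attach to
#'   opposite poles with probability 1 (monopolin loss, mam1),
#'   overriding `p_monoorient`.
#' @param p_transient_cohesion Probability in `[0, 1]` that a bi-oriented,
#'   unprotected, cleavage-competent cell nevertheless keeps its split sister
#'   centromeres in close proximity during the scored interval (residual,
#'   transient cohesion). Default 0; non-zero only where a genotype is known
#'   to show a small close-proximity fraction.
#'
#' @return An object of class `genotype_params`.
#' @seealso [genotype_presets()], [simulate_cell()]
#' @export
genotype_params <- function(name,
                            p_monoorient = 1,
                            protection_on = TRUE,
                            cleavage_on = TRUE,
                            second_division_on = TRUE,
                            p_missegregate_mii = 0,
                            forced_biorientation = FALSE,
                            p_transient_cohesion = 0) {
  check_prob <- function(p, what) {
    if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
      stop("parameter error: `", what, "` must be a single probability in [0, 1]",
           call. = FALSE)
    }
  }
  check_flag <- function(x, what) {
    if (!is.logical(x) || length(x) != 1 || is.na(x)) {
      stop("parameter error: `", what, "` must be TRUE or FALSE", call. = FALSE)
    }
  }
  stopifnot(is.character(name), length(name) == 1)
  check_prob(p_monoorient, "p_monoorient")
  check_prob(p_missegregate_mii, "p_missegregate_mii")
  check_prob(p_transient_cohesion, "p_transient_cohesion")
  check_flag(protection_on, "protection_on")
  check_flag(cleavage_on, "cleavage_on")
  check_flag(second_division_on, "second_division_on")
  check_flag(forced_biorientation, "forced_biorientation")
  structure(
    list(name = name,
         p_monoorient = p_monoorient,
         protection_on = protection_on,
         cleavage_on = cleavage_on,
         second_division_on = second_division_on,
         p_missegregate_mii = p_missegregate_mii,
         forced_biorientation = forced_biorientation,
         p_transient_cohesion = p_transient_cohesion),
    class = "genotype_params"
  )
}

#' @export
print.genotype_params <- function(x, ...) {
  cat("<genotype_params> ", x$name, "\n", sep = "")
  cat("  p_monoorient: ", x$p_monoorient,
      if (x$forced_biorientation) "  (forced biorientation)", "\n", sep = "")
  cat("  protection_on: ", x$protection_on,
      "  cleavage_on: ", x$cleavage_on,
      "  second_division_on: ", x$second_division_on, "\n", sep = "")
  cat("  p_missegregate_mii: ", x$p_missegregate_mii,
      "  p_transient_cohesion: ", x$p_transient_cohesion, "\n", sep = "")
  invisible(x)
}

#' Built-in genotype definitions
#'
#' The eight conditions used throughout: wild type; spo13 (no
#' mono-orientation, no protection, single division); mam1 (forced
#' biorientation, protection intact); spo13 mam1 (forced biorientation, no
#' protection, with a small transient-cohesion fraction); mad2 (wild-type-like
#' segregation, modest meiosis II missegregation); spo13 mad2 (second
#' division restored but unprotected, gross meiosis II missegregation);
#' esp1-2 (separase-dead); spo13 esp1-2 (separase-dead, no
#' mono-orientation).
#'
#' @param name Optional: return a single named preset instead of the full
#'   list.
#' @return A named list of [genotype_params()] objects (or one of them).
#' @export
genotype_presets <- function(name = NULL) {
  presets <- list(
    wild_type = genotype_params("wild_type"),
    spo13d = genotype_params("spo13d", p_monoorient = 0, protection_on = FALSE,
                             second_division_on = FALSE),
    mam1d = genotype_params("mam1d", p_monoorient = 0,
                            forced_biorientation = TRUE),
    spo13d_mam1d = genotype_params("spo13d_mam1d", p_monoorient = 0,
                                   protection_on = FALSE,
                                   second_division_on = FALSE,
                                   forced_biorientation = TRUE,
                                   p_transient_cohesion = 0.1),
    mad2d = genotype_params("mad2d", p_missegregate_mii = 0.05),
    spo13d_mad2d = genotype_params("spo13d_mad2d", p_monoorient = 0,
                                   protection_on = FALSE,
                                   second_division_on = TRUE,
                                   p_missegregate_mii = 0.2),
    esp1_2 = genotype_params("esp1_2", cleavage_on = FALSE,
                             second_division_on = FALSE),
    spo13d_esp1_2 = genotype_params("spo13d_esp1_2", p_monoorient = 0,
                                    protection_on = FALSE,
                                    cleavage_on = FALSE,
                                    second_division_on = FALSE)
  )
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) {
    stop("unknown genotype preset: ", name, call. = FALSE)
  }
  presets[[name]]
}

#' Read genotype parameters from JSON
#'
#' The JSON object carries the fields of [genotype_params()]; missing fields
#' take their defaults.
#'
#' @param path Path to a JSON file.
#' @return A `genotype_params` object.
#' @export
read_genotype_json <- function(path) {
  spec <- jsonlite::fromJSON(path)
  if (is.null(spec$name)) stop("config error: genotype JSON must carry `name`", call. = FALSE)
  args <- spec[intersect(names(spec), names(formals(genotype_params)))]
  do.call(genotype_params, args)
}

#' Write genotype parameters to JSON
#'
#' @param g A `genotype_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_json <- function(g, path) {
  stopifnot(inherits(g, "genotype_params"))
  jsonlite::write_json(unclass(g), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
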