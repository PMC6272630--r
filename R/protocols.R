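#' The docking protocol registry
#'
#' The 17 protocols covered by the benchmark: seven docking programs, each
#' as one or more (search algorithm, scoring function) pairs, sorted
#' alphabetically by abbreviation. `licensed` marks programs that require a
#' commercial license (Glide, GOLD, MOE) and therefore get a dedicated
#' scheduler lane; `score_direction` records each scoring function's
#' published convention ("lower_better" for energy-like scores, e.g. the
#' AutoDock and Vina scoring functions, Glide SP GlideScore, the MOE dG
#' scores, PLANTS and rDock totals; "higher_better" for the GOLD fitness
#' functions), which virtual-screening ranking needs.
#'
#' @return data.frame with columns `program`, `search_algorithm`,
#'   `scoring_function`, `abbreviation`, `licensed`, `score_direction`;
#'   exactly 17 rows, alphabetical by abbreviation.
#' @examples
#' nrow(dock_protocols()) # 17
#' @export
dock_protocols <- function() {
  p <- rbind(
    c("Autodock 4.2", "Genetic Algorithm", "AutoDock SF", "AUTODOCK-ga",
      FALSE, "lower_better"),
    c("Autodock 4.2", "Lamarkian GA", "AutoDock SF", "AUTODOCK-lga",
      FALSE, "lower_better"),
    c("Autodock 4.2", "Local Search", "AutoDock SF", "AUTODOCK-ls",
      FALSE, "lower_better"),
    c("Glide 6.5", "Glide Algorithm", "Standard Precision", "GLIDE-sp",
      TRUE, "lower_better"),
    c("GOLD 5.2", "Genetic Algorithm", "ASP", "GOLD-asp",
      TRUE, "higher_better"),
    c("GOLD 5.2", "Genetic Algorithm", "Chemscore", "GOLD-chemscore",
      TRUE, "higher_better"),
    c("GOLD 5.2", "Genetic Algorithm", "Goldscore", "GOLD-goldscore",
      TRUE, "higher_better"),
    c("GOLD 5.2", "Genetic Algorithm", "PLP", "GOLD-plp",
      TRUE, "higher_better"),
    c("MOE 2014.09", "Triangle Matcher", "Affinity-dG", "MOE-affinitydg",
      TRUE, "lower_better"),
    c("MOE 2014.09", "Triangle Matcher", "GBIVIWSA", "MOE-gbiviwsa",
      TRUE, "lower_better"),
    c("MOE 2014.09", "Triangle Matcher", "London-dG", "MOE-londondg",
      TRUE, "lower_better"),
    c("PLANTS 1.2", "ACO Algorithm", "ChemPLP", "PLANTS-chemplp",
      FALSE, "lower_better"),
    c("PLANTS 1.2", "ACO Algorithm", "PLP", "PLANTS-plp",
      FALSE, "lower_better"),
    c("PLANTS 1.2", "ACO Algorithm", "PLP95", "PLANTS-plp95",
      FALSE, "lower_better"),
    c("rDock 2013.1", "Genetic Algorithm + Monte Carlo + Simplex minimization",
      "Standard rDock master SF + desolvation potential", "RDOCK-solv",
      FALSE, "lower_better"),
    c("rDock 2013.1", "Genetic Algorithm + Monte Carlo + Simplex minimization",
      "Standard rDock master SF", "RDOCK-std",
      FALSE, "lower_better"),
    c("AutoDock Vina 1.1.2", "Monte Carlo + BFGS local search",
      "Standard Vina SF", "VINA-std",
      FALSE, "lower_better")
  )
  out <- data.frame(
    program = p[, 1], search_algorithm = p[, 2], scoring_function = p[, 3],
    abbreviation = p[, 4], licensed = as.logical(p[, 5]),
    score_direction = p[, 6], stringsAsFactors = FALSE
  )
  stopifnot(!is.unsorted(out$abbreviation))
  out
}

#' Program name for protocol abbreviations
#'
#' The program token of an abbreviation (the part before the first hyphen),
#' used to route jobs to scheduler lanes.
#'
#' @param abbrev character vector of protocol abbreviations.
#' @return character vector of program tokens (e.g. "GOLD").
#' @export
protocol_program <- function(abbrev) {
  sub("-.*$", "", abbrev)
}
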