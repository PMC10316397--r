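# Decision logic mapping the per-subunit alpha/pi composition of the S6
# bundle to a conductance class and a functional-state assignment.

SUBUNITS <- c("DI", "DII", "DIII", "DIV")

#' Parse a pore-model name into its alpha/pi composition
#'
#' Model names follow the convention `<k>pi(_d<j>)*`: the prefix gives the
#' number of pi-helices and the `_d` parts say which S6 helices carry them
#' (e.g. `"2pi_d1_d3"` = pi in DI and DIII; `"4pi"` = pi in all four).
#'
#' @param name Model name string.
#' @return A `pore_state_composition`: tibble with columns `model_name`,
#'   `DI`, `DII`, `DIII`, `DIV` (each `"alpha"` or `"pi"`), `n_pi`.
#' @export
#' @examples
#' parse_model_name("2pi_d1_d3")
parse_model_name <- function(name) {
  if (length(name) != 1L || !is.character(name)) {
    rlang::abort("`name` must be a single string.")
  }
  if (!grepl("^[0-4]pi(_d[1-4])*$", name)) {
    rlang::abort(sprintf("'%s' does not match '<k>pi(_d[1-4])*'.", name))
  }
  k <- as.integer(substr(name, 1, 1))
  toks <- strsplit(name, "_")[[1]][-1]
  idx <- as.integer(sub("d", "", toks))
  if (anyDuplicated(idx)) {
    rlang::abort(sprintf("'%s' lists a subunit twice.", name))
  }
  if (length(idx) == 0L && k == 4L) idx <- 1:4 # "4pi": pi in all four S6s
  if (length(idx) != k) {
    rlang::abort(sprintf(
      "'%s': count prefix says %d pi-helices but %d subunits are listed.",
      name, k, length(idx)))
  }
  labels <- rep("alpha", 4)
  labels[idx] <- "pi"
  out <- tibble::tibble(model_name = name, DI = labels[1], DII = labels[2],
                        DIII = labels[3], DIV = labels[4], n_pi = k)
  structure(out, class = c("pore_state_composition", class(tibble::tibble())))
}

#' Format a composition back into its model name
#'
#' Inverse of [parse_model_name()]: round-trips exactly for all 16
#' compositions.
#'
#' @param composition A `pore_state_composition` (or tibble with DI..DIV).
#' @return Model name string.
#' @export
format_model_name <- function(composition) {
  labels <- unlist(composition[1, SUBUNITS])
  idx <- which(labels == "pi")
  if (length(idx) == 4L) return("4pi")
  paste0(length(idx), "pi",
         paste0(purrr::map_chr(idx, function(i) paste0("_d", i)), collapse = ""))
}

#' Classify a pore composition into a conductance class
#'
#' Encodes the experimental-model decision logic: with a pi-helix in
#' DIII-S6 (present in every resolved Nav conformation), a pi-helix in
#' both DI-S6 and DIV-S6 gives a fully conductive pore; a pi-helix in
#' exactly one of DI/DIV gives a subconductance pore; in neither, a
#' nonconducting pore. DII-S6 never changes the class — a pi-helix there
#' is not essential for ion permeation. Compositions with an alpha-helical
#' DIII-S6 are outside the modeled space (never tested) and are flagged
#' rather than extrapolated.
#'
#' @param composition A `pore_state_composition` or model-name string.
#' @return A `conductance_class` tibble: `model_name`, `n_pi`, `class`
#'   (`"fully_conductive"`, `"subconductance"`, `"nonconducting"`, or NA),
#'   `modeled` (FALSE for DIII = alpha), `functional_label`.
#' @export
#' @examples
#' classify_pore_state("4pi")$class
#' classify_pore_state("2pi_d2_d3")$class
classify_pore_state <- function(composition) {
  comp <- if (is.character(composition)) parse_model_name(composition) else composition
  if (!all(SUBUNITS %in% names(comp))) {
    rlang::abort("`composition` must carry DI, DII, DIII, DIV labels.")
  }
  if (comp$DIII != "pi") {
    rlang::warn(sprintf(
      "%s: DIII-S6 is alpha-helical — outside the modeled space; no class assigned.",
      comp$model_name))
    cls <- NA_character_
    modeled <- FALSE
  } else {
    modeled <- TRUE
    di <- comp$DI == "pi"; div <- comp$DIV == "pi"
    cls <- if (di && div) "fully_conductive"
           else if (di || div) "subconductance"
           else "nonconducting"
  }
  out <- tibble::tibble(
    model_name = comp$model_name,
    n_pi = comp$n_pi,
    class = cls,
    modeled = modeled
  )
  out$functional_label <- functional_label_of(comp, cls)
  structure(out, class = c("conductance_class", class(tibble::tibble())))
}

functional_label_of <- function(comp, cls) {
  if (is.na(cls)) return("none")
  if (cls == "fully_conductive") return("O (first open) candidate")
  if (cls == "subconductance" && comp$n_pi == 2) {
    # 2pi_d1_d3 (the experimentally captured open structure) and 2pi_d3_d4
    return("S2 (second open) candidate")
  }
  "none"
}

#' Functional-state assignment of a composition
#'
#' Fully conductive compositions are candidates for the first open state
#' (O); the two-pi subconductance compositions `2pi_d1_d3` (the
#' experimentally captured open structure) and `2pi_d3_d4` are candidates
#' for the second open state (S2). Everything else gets `"none"`. The
#' labels are advisory strings, not classes.
#'
#' @inheritParams classify_pore_state
#' @return A single string.
#' @export
assign_functional_state <- function(composition) {
  classify_pore_state(composition)$functional_label
}

#' Expected conductance ranking of compositions
#'
#' Partial order with conductance class as the primary key and pi count as
#' the secondary key (pore conductance tracks the number of pi-helices in
#' the S6 bundle). Ties — same class and same pi count — are reported as
#' equal ranks.
#'
#' @param compositions Character vector of model names (length >= 1).
#' @return Tibble `model_name`, `class`, `n_pi`, `rank` (1 = highest
#'   expected conductance; equal values mark ties).
#' @export
#' @examples
#' expected_rank(c("4pi", "2pi_d1_d3", "1pi_d3"))
expected_rank <- function(compositions) {
  rows <- purrr::map(compositions, function(nm) classify_pore_state(nm))
  d <- dplyr::bind_rows(rows)
  class_score <- c(fully_conductive = 3, subconductance = 2, nonconducting = 1)
  d$score <- unname(class_score[d$class]) * 10 + d$n_pi
  d$score[is.na(d$score)] <- -Inf
  d$rank <- match(-d$score, sort(unique(-d$score)))
  d[, c("model_name", "class", "n_pi", "rank")]
}

#' All 16 alpha/pi compositions of the S6 bundle
#'
#' @return Tibble with `model_name`, DI..DIV labels and `n_pi` for every
#'   subset of subunits carrying a pi-helix.
#' @export
all_compositions <- function() {
  grid <- expand.grid(DI = c("alpha", "pi"), DII = c("alpha", "pi"),
                      DIII = c("alpha", "pi"), DIV = c("alpha", "pi"),
                      stringsAsFactors = FALSE)
  purrr::map(seq_len(nrow(grid)), function(i) {
    labels <- unlist(grid[i, ])
    idx <- which(labels == "pi")
    nm <- if (length(idx) == 4L) "4pi" else
      paste0(length(idx), "pi",
             paste0(purrr::map_chr(idx, function(j) paste0("_d", j)),
                    collapse = ""))
    tibble::tibble(model_name = nm, DI = labels[1], DII = labels[2],
                   DIII = labels[3], DIV = labels[4], n_pi = length(idx))
  }) |> dplyr::bind_rows()
}
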