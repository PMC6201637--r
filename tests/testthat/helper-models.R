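# small model builders shared across test files

# toy model plus a parallel product branch B -> B2 -> P
branched_toy_model <- function() {
  m <- toy_model()
  rx <- dplyr::bind_rows(
    m$reactions[c("id", "lower_bound", "upper_bound", "gpr")],
    tibble::tibble(id = c("R_alt1", "R_alt2"), lower_bound = 0,
                   upper_bound = 1000, gpr = c("gX1", "gX2")))
  st <- dplyr::bind_rows(m$stoichiometry, tibble::tribble(
    ~reaction, ~metabolite, ~coefficient,
    "R_alt1", "B", -1, "R_alt1", "B2", 1,
    "R_alt2", "B2", -1, "R_alt2", "P", 1))
  metabolic_model(rx, st, biomass_id = "R_bio", target_id = "EX_P")
}

# linear chain with an internal 2-reaction futile cycle X <-> Y
cycle_model <- function() {
  rx <- tibble::tribble(
    ~id,      ~lower_bound, ~upper_bound, ~gpr,
    "EX_in",  0, 5,    NA_character_,
    "cyc_f",  0, 1000, "g1",
    "cyc_b",  0, 1000, "g2",
    "EX_out", 0, 1000, NA_character_)
  st <- tibble::tribble(
    ~reaction, ~metabolite, ~coefficient,
    "EX_in",  "X",  1,
    "cyc_f",  "X", -1, "cyc_f", "Y",  1,
    "cyc_b",  "Y", -1, "cyc_b", "X",  1,
    "EX_out", "Y", -1)
  metabolic_model(rx, st, biomass_id = "EX_out", target_id = "EX_out")
}

scale_model_bounds <- function(model, c) {
  model$reactions$lower_bound <- model$reactions$lower_bound * c
  model$reactions$upper_bound <- model$reactions$upper_bound * c
  model
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
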