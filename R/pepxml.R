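#' Read a minimal PSM set from a pepXML file
#'
#' A deliberately minimal pepXML reader covering the fields quantification
#' needs: spectrum id, peptide with modifications (re-encoded as bracketed
#' masses, e.g. `M[+15.9949]`), assumed charge, theoretical m/z (from
#' `calc_neutral_pep_mass`), retention time, ion mobility (from the
#' `ion_mobility` attribute when present), and protein accessions
#' (including `alternative_protein` entries, semicolon-joined). Only the
#' top-ranked hit of each spectrum query is kept. PSMs are expected to be
#' FDR-filtered upstream; no score filtering happens here.
#'
#' @param path Path to a pepXML file.
#' @param run_id Run label; defaults to the `msms_run_summary` base name.
#' @return A PSM tibble as from [read_psm_table()].
#' @export
read_pepxml <- function(path, run_id = NULL) {
  stopifnot(file.exists(path))
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(paste0("malformed pepXML in ", path, ": ", conditionMessage(e)),
          class = "lfq4d_format_error")
  })
  xml2::xml_ns_strip(doc)
  runs <- xml2::xml_find_all(doc, ".//msms_run_summary")
  if (!length(runs)) {
    abort(paste0(path, ": no msms_run_summary element"),
          class = "lfq4d_format_error")
  }
  out <- lapply(runs, function(run_node) {
    rid <- run_id
    if (is.null(rid)) {
      rid <- basename(xml2::xml_attr(run_node, "base_name"))
      if (is.na(rid)) rid <- sub("\\.[^.]*$", "", basename(path))
    }
    queries <- xml2::xml_find_all(run_node, ".//spectrum_query")
    rows <- lapply(queries, function(q) {
      hit <- xml2::xml_find_first(q, ".//search_hit[@hit_rank='1']")
      if (inherits(hit, "xml_missing")) {
        hit <- xml2::xml_find_first(q, ".//search_hit")
      }
      if (inherits(hit, "xml_missing")) return(NULL)
      charge <- as.integer(xml2::xml_attr(q, "assumed_charge"))
      neutral <- as.numeric(xml2::xml_attr(hit, "calc_neutral_pep_mass"))
      rt_sec <- as.numeric(xml2::xml_attr(q, "retention_time_sec"))
      im <- as.numeric(xml2::xml_attr(q, "ion_mobility"))
      peptide <- pepxml_modified_peptide(hit)
      prots <- c(xml2::xml_attr(hit, "protein"),
                 xml2::xml_attr(
                   xml2::xml_find_all(hit, "./alternative_protein"),
                   "protein"))
      tibble(
        run_id = rid,
        spectrum_id = xml2::xml_attr(q, "spectrum"),
        peptide = peptide, charge = charge,
        theoretical_mz = (neutral + charge * PROTON_MASS) / charge,
        rt = rt_sec / 60, im = im,
        proteins = paste(prots[!is.na(prots)], collapse = ";"),
        organism = NA_character_
      )
    })
    bind_rows(rows)
  })
  bind_rows(out)
}

# inline bracketed-mass encoding of a search_hit's modifications
pepxml_modified_peptide <- function(hit) {
  pep <- xml2::xml_attr(hit, "peptide")
  mods <- xml2::xml_find_all(hit, ".//mod_aminoacid_mass")
  if (!length(mods)) return(pep)
  pos <- as.integer(xml2::xml_attr(mods, "position"))
  mass <- as.numeric(xml2::xml_attr(mods, "mass"))
  residues <- strsplit(pep, "")[[1]]
  # mod_aminoacid_mass@mass is residue + modification; report the residue
  # with its total mass as M[mass] to keep the ion key unambiguous
  ord <- order(pos, decreasing = TRUE)
  for (i in ord) {
    residues[pos[i]] <- sprintf("%s[%.4f]", residues[pos[i]], mass[i])
  }
  paste0(residues, collapse = "")
}
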