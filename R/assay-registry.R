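#' Define a duplex ddPCR blood-group assay
#'
#' An assay maps the two fluorescence channels of a duplex droplet digital
#' PCR reaction to allele labels. Channel 1 is the FAM (blue) fluorophore,
#' channel 2 the HEX/VIC (green) fluorophore. For the RHD assay the HEX
#' channel carries a non-polymorphic total-DNA control (beta-globin), which
#' downstream code must treat as counting maternal plus fetal genomes.
#'
#' @param name Assay identifier, unique within a registry.
#' @param gene Gene symbol (e.g. `"RHD"`, `"RHCE"`, `"KEL"`).
#' @param snp_id dbSNP rs identifier, or `"deletion"` for the RHD
#'   presence/absence assay.
#' @param fam_allele Allele label detected in the FAM channel.
#' @param hex_allele Allele label detected in the HEX channel.
#' @param amplicon_length_bp Amplicon length in base pairs (annotation).
#' @param reference_channel_is_total_dna Logical; `TRUE` only when the HEX
#'   channel is a total-DNA control locus rather than the other allele of a
#'   SNP.
#' @param null_allele Label of the null allele for presence/absence assays
#'   (`NA` for SNP assays). A mother homozygous for the null allele carries
#'   no copy of the FAM target.
#' @param metadata Optional named list of inert annotation (primer/probe
#'   sequences etc.); never used in computation.
#'
#' @return An object of class `assay_definition`.
#' @seealso [builtin_assays()], [maternal_context()], [fetus_specific_channel()]
#' @export
#' @examples
#' assay_definition("KEL_rs8176058", "KEL", "rs8176058",
#'                  fam_allele = "KEL1", hex_allele = "KEL2",
#'                  amplicon_length_bp = 65)
assay_definition <- function(name, gene, snp_id, fam_allele, hex_allele,
                             amplicon_length_bp = NA_integer_,
                             reference_channel_is_total_dna = FALSE,
                             null_allele = NA_character_,
                             metadata = list()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.character(fam_allele) || !is.character(hex_allele) ||
      length(fam_allele) != 1L || length(hex_allele) != 1L) {
    stop("assay '", name, "': fam_allele and hex_allele must be single strings",
         call. = FALSE)
  }
  if (identical(fam_allele, hex_allele)) {
    stop("assay '", name, "': fam_allele and hex_allele must differ (got '",
         fam_allele, "' for both)", call. = FALSE)
  }
  if (isTRUE(reference_channel_is_total_dna) && is.na(null_allele)) {
    stop("assay '", name, "': a total-DNA reference channel requires a ",
         "null_allele for the target locus", call. = FALSE)
  }
  structure(
    list(
      name = name,
      gene = gene,
      snp_id = snp_id,
      fam_allele = fam_allele,
      hex_allele = hex_allele,
      amplicon_length_bp = as.integer(amplicon_length_bp),
      reference_channel_is_total_dna = isTRUE(reference_channel_is_total_dna),
      null_allele = null_allele,
      metadata = metadata
    ),
    class = "assay_definition"
  )
}

#' @export
print.assay_definition <- function(x, ...) {
  cat("<assay_definition> ", x$name, " (", x$gene, ", ", x$snp_id, ")\n",
      "  FAM: ", x$fam_allele, "   HEX: ", x$hex_allele,
      if (x$reference_channel_is_total_dna) "  [HEX = total-DNA control]",
      "\n", sep = "")
  invisible(x)
}

#' Built-in assay registry
#'
#' The four duplex assays used for noninvasive fetal blood-group
#' genotyping: RHD exon 7 against a beta-globin total-DNA control, the two
#' RHCE SNP assays (C/c at rs676785, E/e at rs609320) and the KEL1/KEL2
#' assay at rs8176058. In each duplex the FAM (blue) channel detects the
#' allele listed first below and the HEX (green) channel the second.
#'
#' * `RHD_ex7` — FAM: RHD exon 7; HEX: beta-globin (total-DNA control).
#' * `RHCE_rs609320` — FAM: e; HEX: E.
#' * `RHCE_rs676785` — FAM: c; HEX: C.
#' * `KEL_rs8176058` — FAM: KEL1; HEX: KEL2.
#'
#' @return A named list of [assay_definition] objects.
#' @export
#' @examples
#' names(builtin_assays())
#' builtin_assays()$RHD_ex7
builtin_assays <- function() {
  assays <- list(
    assay_definition(
      name = "RHD_ex7", gene = "RHD", snp_id = "deletion",
      fam_allele = "RHD", hex_allele = "beta-globin",
      amplicon_length_bp = 72L,
      reference_channel_is_total_dna = TRUE,
      null_allele = "RHD-"
    ),
    assay_definition(
      name = "RHCE_rs609320", gene = "RHCE", snp_id = "rs609320",
      fam_allele = "e", hex_allele = "E", amplicon_length_bp = 64L
    ),
    assay_definition(
      name = "RHCE_rs676785", gene = "RHCE", snp_id = "rs676785",
      fam_allele = "c", hex_allele = "C", amplicon_length_bp = 74L
    ),
    assay_definition(
      name = "KEL_rs8176058", gene = "KEL", snp_id = "rs8176058",
      fam_allele = "KEL1", hex_allele = "KEL2", amplicon_length_bp = 65L
    )
  )
  stats::setNames(assays, vapply(assays, `[[`, "", "name"))
}

#' Load an assay registry from a configuration file
#'
#' Reads a YAML (or pre-parsed list) describing one or more duplex assays
#' and returns them merged over the built-in registry. Each entry must
#' provide `name`, `gene`, `snp_id`, `fam_allele` and `hex_allele`;
#' `amplicon_length_bp`, `reference_channel_is_total_dna`, `null_allele`
#' and `metadata` are optional. The built-in assays are always available;
#' passing `NULL` returns them unchanged.
#'
#' @param config_source Path to a YAML file, a YAML string, or a list of
#'   assay entries; `NULL` for built-ins only.
#' @param include_builtin Keep the built-in assays alongside the configured
#'   ones (default `TRUE`). A configured assay may not reuse a built-in
#'   name.
#' @return Named list of [assay_definition] objects.
#' @export
load_assays <- function(config_source = NULL, include_builtin = TRUE) {
  registry <- if (include_builtin) builtin_assays() else list()
  if (is.null(config_source)) {
    return(registry)
  }
  entries <- if (is.list(config_source)) {
    config_source
  } else {
    parsed <- yaml::yaml.load_file(config_source)
    if (is.list(parsed) && !is.null(parsed$assays)) parsed$assays else parsed
  }
  if (!is.list(entries) || length(entries) == 0L) {
    stop("assay config is empty or not a list of assay entries", call. = FALSE)
  }
  required <- c("name", "gene", "snp_id", "fam_allele", "hex_allele")
  for (entry in entries) {
    if (!is.list(entry)) {
      stop("assay config entry is not a mapping of fields", call. = FALSE)
    }
    missing <- setdiff(required, names(entry))
    if (length(missing) > 0L) {
      stop("assay config entry ",
           if (!is.null(entry$name)) paste0("'", entry$name, "' "),
           "is missing field(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    def <- assay_definition(
      name = entry$name, gene = entry$gene, snp_id = entry$snp_id,
      fam_allele = entry$fam_allele, hex_allele = entry$hex_allele,
      amplicon_length_bp = entry$amplicon_length_bp %||% NA_integer_,
      reference_channel_is_total_dna =
        entry$reference_channel_is_total_dna %||% FALSE,
      null_allele = entry$null_allele %||% NA_character_,
      metadata = entry$metadata %||% list()
    )
    if (def$name %in% names(registry)) {
      stop("duplicate assay name '", def$name, "' in registry", call. = FALSE)
    }
    registry[[def$name]] <- def
  }
  registry
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a genotype string into an allele pair
#'
#' Accepts either a slash-separated pair (`"KEL2/KEL2"`, `"RHD-/RHD-"`), a
#' two-character shorthand for single-letter alleles (`"cc"`, `"Cc"`,
#' `"Ee"`), or a character vector of two allele labels.
#'
#' @param genotype Genotype in any of the accepted forms.
#' @return Character vector of two allele labels.
#' @export
parse_genotype <- function(genotype) {
  if (is.character(genotype) && length(genotype) == 2L) {
    return(genotype)
  }
  if (!is.character(genotype) || length(genotype) != 1L) {
    stop("genotype must be a single string or a pair of allele labels",
         call. = FALSE)
  }
  if (grepl("/", genotype, fixed = TRUE)) {
    alleles <- strsplit(genotype, "/", fixed = TRUE)[[1L]]
    if (length(alleles) != 2L || !all(nzchar(alleles))) {
      stop("cannot parse genotype '", genotype, "' as two '/'-separated alleles",
           call. = FALSE)
    }
    return(alleles)
  }
  if (nchar(genotype) == 2L) {
    return(strsplit(genotype, "")[[1L]])
  }
  stop("cannot parse genotype '", genotype,
       "'; use 'allele1/allele2' or two-letter shorthand", call. = FALSE)
}

#' Maternal analysis context for one assay
#'
#' Couples an assay with the maternal genotype at its locus. The analysis
#' model requires the mother to be homozygous: every positive droplet in
#' the channel of the allele she lacks can then only come from fetal DNA
#' or from noise. A heterozygous maternal genotype is rejected because the
#' fetal signal would be indistinguishable from the maternal background.
#'
#' For the RHD presence/absence assay, the only valid maternal genotype is
#' homozygous RHD-negative (`"RHD-/RHD-"`, the whole-gene deletion typical
#' of RhD-negative Europeans); an RHD-positive mother saturates the FAM
#' channel with her own signal.
#'
#' @param assay An [assay_definition] (or the name of a built-in assay).
#' @param maternal_genotype Genotype in any form accepted by
#'   [parse_genotype()]; must be homozygous and composed of the assay's
#'   allele labels (or its null allele).
#' @return An object of class `maternal_context`.
#' @export
#' @examples
#' maternal_context("RHCE_rs676785", "cc")
#' maternal_context(builtin_assays()$RHD_ex7, "RHD-/RHD-")
maternal_context <- function(assay, maternal_genotype) {
  if (is.character(assay) && length(assay) == 1L) {
    registry <- builtin_assays()
    if (!assay %in% names(registry)) {
      stop("unknown assay '", assay, "'; built-ins are: ",
           paste(names(registry), collapse = ", "), call. = FALSE)
    }
    assay <- registry[[assay]]
  }
  if (!inherits(assay, "assay_definition")) {
    stop("'assay' must be an assay_definition or a built-in assay name",
         call. = FALSE)
  }
  alleles <- parse_genotype(maternal_genotype)
  if (alleles[1L] != alleles[2L]) {
    stop("maternal genotype '", paste(alleles, collapse = "/"),
         "' is heterozygous; the analysis assumes a homozygous mother",
         call. = FALSE)
  }
  valid <- c(assay$fam_allele,
             if (!assay$reference_channel_is_total_dna) assay$hex_allele,
             if (!is.na(assay$null_allele)) assay$null_allele)
  if (!alleles[1L] %in% valid) {
    stop("maternal allele '", alleles[1L], "' is not an allele of assay '",
         assay$name, "' (valid: ", paste(valid, collapse = ", "), ")",
         call. = FALSE)
  }
  if (assay$reference_channel_is_total_dna &&
      alleles[1L] == assay$fam_allele) {
    stop("assay '", assay$name, "': a mother carrying the '",
         assay$fam_allele, "' target cannot be analysed; fetal signal in ",
         "the FAM channel would be masked by the maternal background",
         call. = FALSE)
  }
  structure(
    list(assay = assay, maternal_genotype = alleles),
    class = "maternal_context"
  )
}

#' @export
print.maternal_context <- function(x, ...) {
  fs <- fetus_specific_channel(x)
  cat("<maternal_context> assay ", x$assay$name, ", mother ",
      paste(x$maternal_genotype, collapse = "/"),
      "\n  fetus-specific channel: ", fs$channel, " (allele ", fs$allele,
      ")\n", sep = "")
  invisible(x)
}

#' Resolve the fetus-specific channel for a maternal context
#'
#' Given a homozygous mother, exactly one channel of the duplex detects an
#' allele she does not carry; positives there can only originate from the
#' fetus (or from false-positive noise). The other channel is the
#' maternal/reference channel. For the RHD assay the fetus-specific channel
#' is always FAM (the RHD target) and the reference channel is the
#' beta-globin total-DNA control.
#'
#' @param ctx A [maternal_context].
#' @return A list with elements `channel` (`"FAM"` or `"HEX"`), `allele`
#'   (the fetus-specific allele label), `maternal_channel` and
#'   `maternal_allele` (for the RHD assay the maternal channel allele is
#'   the control locus), and `reference_is_total_dna`.
#' @export
#' @examples
#' fetus_specific_channel(maternal_context("RHCE_rs676785", "cc"))
fetus_specific_channel <- function(ctx) {
  if (!inherits(ctx, "maternal_context")) {
    stop("'ctx' must be a maternal_context", call. = FALSE)
  }
  assay <- ctx$assay
  m <- ctx$maternal_genotype[1L]
  if (assay$reference_channel_is_total_dna) {
    # presence/absence assay: valid contexts carry the null allele only
    fs_channel <- "FAM"
    fs_allele <- assay$fam_allele
    mat_channel <- "HEX"
    mat_allele <- assay$hex_allele
  } else if (m == assay$fam_allele) {
    fs_channel <- "HEX"
    fs_allele <- assay$hex_allele
    mat_channel <- "FAM"
    mat_allele <- assay$fam_allele
  } else {
    fs_channel <- "FAM"
    fs_allele <- assay$fam_allele
    mat_channel <- "HEX"
    mat_allele <- assay$hex_allele
  }
  list(
    channel = fs_channel,
    allele = fs_allele,
    maternal_channel = mat_channel,
    maternal_allele = mat_allele,
    reference_is_total_dna = assay$reference_channel_is_total_dna
  )
}
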