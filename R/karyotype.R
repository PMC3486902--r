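# ISCN-subset karyotype parsing.
#
# Grammar: "<45|46>,<XX|XY>,<event>" with an optional second
# "/"-separated constitution for couples in which both partners carry a
# rearrangement. Events: t(a;b)(bands), der(a;b)(q10;q10), inv(a)(bands).
# Breakpoint bands are preserved verbatim but never interpreted; only
# chromosome identity feeds the downstream exclusion rule.

EVENT_RE <- "^(t|der|inv)\\(([^()]*)\\)(?:\\(([^()]*)\\))?$"

parse_segment <- function(segment, karyotype) {
  parts <- stringr::str_match(
    segment,
    "^(4[56]),(XX|XY),(.+)$"
  )
  if (is.na(parts[1, 1])) {
    abort(sprintf(
      "malformed karyotype '%s': segment '%s' does not match '<45|46>,<XX|XY>,<event>'",
      karyotype, segment
    ))
  }
  modal_n <- as.integer(parts[1, 2])
  sex_code <- parts[1, 3]
  event <- parts[1, 4]

  m <- stringr::str_match(event, EVENT_RE)
  if (is.na(m[1, 1])) {
    # name the offending token: either an unsupported event type or junk
    head_tok <- stringr::str_match(event, "^([a-z]+)\\(")[1, 2]
    if (!is.na(head_tok)) {
      abort(sprintf(
        "unsupported rearrangement type '%s' in karyotype '%s' (supported: t, der, inv)",
        head_tok, karyotype
      ))
    }
    abort(sprintf("malformed karyotype '%s': cannot parse event '%s'", karyotype, event))
  }
  op <- m[1, 2]
  chroms <- stringr::str_split_1(m[1, 3], ";")
  bands <- m[1, 4] # may be NA; opaque

  bad <- setdiff(chroms, CHROM_LABELS)
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid chromosome label '%s' in karyotype '%s'",
      bad[[1]], karyotype
    ))
  }

  if (op == "inv") {
    if (length(chroms) != 1) {
      abort(sprintf(
        "inversion in karyotype '%s' must involve exactly 1 chromosome, got %d",
        karyotype, length(chroms)
      ))
    }
    kind <- "inversion"
  } else {
    if (length(chroms) != 2 || chroms[[1]] == chroms[[2]]) {
      abort(sprintf(
        "'%s' event in karyotype '%s' must involve exactly 2 distinct chromosomes",
        op, karyotype
      ))
    }
    if (op == "der") {
      # only centromeric-fusion derivatives are in scope
      if (is.na(bands) || bands != "q10;q10") {
        abort(sprintf(
          "unsupported rearrangement: der(%s) in karyotype '%s' without (q10;q10) breakpoints",
          m[1, 3], karyotype
        ))
      }
      kind <- "robertsonian"
    } else {
      kind <- "reciprocal"
    }
  }

  tibble(
    modal_n = modal_n,
    carrier_sex = ifelse(sex_code == "XY", "male", "female"),
    kind = kind,
    chrom_1 = chroms[[1]],
    chrom_2 = if (length(chroms) == 2) chroms[[2]] else NA_character_,
    breakpoints = bands,
    # a reciprocal-notation translocation between two acrocentrics could be a
    # Robertsonian written as t(); flagged, never silently reclassified
    acrocentric_candidate = kind == "reciprocal" &&
      all(chroms %in% ACROCENTRICS)
  )
}

#' Parse ISCN-subset karyotype strings into structured rearrangements
#'
#' Understands the karyotype notation used for carrier couples in
#' preimplantation genetic diagnosis referrals: a modal chromosome number (45
#' or 46), a sex designation (XX or XY), and a single rearrangement event —
#' `t(a;b)(bands)` for reciprocal translocations, `der(a;b)(q10;q10)` for
#' Robertsonian (centromeric-fusion) translocations, or `inv(a)(bands)` for
#' inversions. Two `/`-separated constitutions denote a couple in which both
#' partners carry a rearrangement; each contributes one event row.
#'
#' Breakpoint bands are stored verbatim and never interpreted. Reciprocal
#' translocations joining two acrocentric chromosomes (13, 14, 15, 21, 22)
#' are flagged via `acrocentric_candidate` because by convention such events
#' are sometimes regarded as Robertsonian; the parser never reclassifies
#' them.
#'
#' @param x Character vector of karyotype strings.
#' @return A tibble with one row per rearrangement event: `karyotype` (the
#'   input string), `segment` (which `/`-separated constitution the event
#'   came from), `modal_n`, `carrier_sex` (`"male"`/`"female"`, from the
#'   segment's sex designation), `kind` (`"robertsonian"`, `"reciprocal"`,
#'   `"inversion"`), `chrom_1`, `chrom_2` (`NA` for inversions),
#'   `breakpoints` (verbatim band string), and `acrocentric_candidate`.
#' @export
#' @examples
#' parse_karyotype("45,XY,der(13;14)(q10;q10)")
#' parse_karyotype("46,XY,t(5;15)(q13.1;q21.2)/46,XX,inv(3)(q25.1;q26.2)")
parse_karyotype <- function(x) {
  stopifnot(is.character(x))
  purrr::imap_dfr(x, function(kt, j) {
    if (is.na(kt) || !nzchar(kt)) {
      abort("karyotype string is missing or empty")
    }
    segments <- stringr::str_split_1(kt, "/")
    purrr::imap_dfr(segments, function(seg, i) {
      mutate(parse_segment(seg, kt),
        input = j, karyotype = kt, segment = i,
        .before = 1
      )
    })
  })
}

#' Re-serialize parsed rearrangements to karyotype strings
#'
#' Inverse of [parse_karyotype()]: rebuilds one karyotype string per input
#' karyotype from the event table, so `parse -> format -> parse` is the
#' identity on the supported grammar.
#'
#' @param events A tibble as returned by [parse_karyotype()].
#' @return Character vector with one karyotype string per input element (the
#'   `input` column), in input order.
#' @export
format_karyotype <- function(events) {
  fmt_one <- function(df) {
    segs <- df %>%
      arrange(.data$segment) %>%
      mutate(
        op = dplyr::case_match(
          .data$kind,
          "robertsonian" ~ "der",
          "reciprocal" ~ "t",
          "inversion" ~ "inv"
        ),
        chrom_part = ifelse(
          is.na(.data$chrom_2), .data$chrom_1,
          paste0(.data$chrom_1, ";", .data$chrom_2)
        ),
        band_part = ifelse(is.na(.data$breakpoints), "",
          paste0("(", .data$breakpoints, ")")
        ),
        sex_code = ifelse(.data$carrier_sex == "male", "XY", "XX"),
        text = paste0(
          .data$modal_n, ",", .data$sex_code, ",",
          .data$op, "(", .data$chrom_part, ")", .data$band_part
        )
      )
    paste(segs$text, collapse = "/")
  }
  events %>%
    group_by(.data$input) %>%
    dplyr::group_split() %>%
    purrr::map_chr(fmt_one)
}

#' Carrier sex recorded for a karyotype
#'
#' For a single-constitution karyotype this is the sex designation of the
#' string carrying the rearrangement. For a compound couple (two
#' `/`-separated constitutions with different sex designations) the case is
#' recorded as `"both"` and is excluded from sex-stratified inference.
#'
#' @param x Character vector of karyotype strings.
#' @return Character vector: `"male"`, `"female"` or `"both"`.
#' @export
karyotype_sex <- function(x) {
  ux <- unique(x)
  events <- parse_karyotype(ux)
  sex_of <- function(kt) {
    s <- unique(events$carrier_sex[events$karyotype == kt])
    if (length(s) > 1) "both" else s
  }
  out <- vapply(ux, sex_of, character(1))
  unname(out[match(x, ux)])
}

#' Chromosomes excluded from aneuploidy assessment for a carrier
#'
#' The chromosomes involved in a patient's rearrangement(s) cannot be scored
#' for incidental malsegregation — abnormalities affecting them are expected
#' consequences of the rearrangement itself — so they are excluded from both
#' the patient's and the matched control group's tallies. The exclusion set
#' is the union of involved chromosomes across all of the carrier couple's
#' rearrangements.
#'
#' @param x Character vector of karyotype strings, or a parsed event tibble
#'   from [parse_karyotype()].
#' @return A list (one element per karyotype) of sorted chromosome labels.
#' @export
#' @examples
#' excluded_chromosomes("45,XY,der(13;14)(q10;q10)")[[1]]
#' excluded_chromosomes("46,XY,t(5;15)(q13.1;q21.2)/46,XX,inv(3)(q25.1;q26.2)")[[1]]
excluded_chromosomes <- function(x) {
  events <- if (is.data.frame(x)) x else parse_karyotype(x)
  keys <- if (is.data.frame(x)) unique(events$karyotype) else x
  lapply(keys, function(kt) {
    ev <- events[events$karyotype == kt, ]
    chroms <- unique(stats::na.omit(c(ev$chrom_1, ev$chrom_2)))
    chroms[order(match(chroms, CHROM_LABELS))]
  })
}

#' Rearrangement class of a carrier case
#'
#' Collapses a karyotype's event list to a single case-level class label:
#' the event's kind for single-rearrangement carriers, `"compound"` when the
#' couple carries two rearrangements.
#'
#' @param x Character vector of karyotype strings.
#' @return Character vector: `"robertsonian"`, `"reciprocal"`,
#'   `"inversion"`, or `"compound"`.
#' @export
rearrangement_class <- function(x) {
  ux <- unique(x)
  events <- parse_karyotype(ux)
  class_of <- function(kt) {
    k <- events$kind[events$karyotype == kt]
    if (length(k) > 1) "compound" else k
  }
  out <- vapply(ux, class_of, character(1))
  unname(out[match(x, ux)])
}
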