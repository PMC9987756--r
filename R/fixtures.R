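#' Published species scoring panel (worked example)
#'
#' Returns the published worked-example z-score panel used to characterise
#' the four oral-gut community types (SB, SP, HB, HP): 14 oral species
#' (9 beneficial with plain z-scores, 5 harmful with sign-reversed
#' z-scores) and 15 gut species (10 beneficial, 5 harmful reversed).
#' Harmful rows are stored post-reversal, exactly as printed, so the
#' matrix feeds [score_panel] directly.
#'
#' @param site `"oral"`, `"gut"` or `"both"`.
#' @return A list with `z` (species x type matrix, columns SB/SP/HB/HP),
#'   and `panel` (a [species_panel] giving each species' role and site).
#' @export
scoring_panel_fixture <- function(site = c("both", "oral", "gut")) {
  site <- match.arg(site)
  types <- c("SB", "SP", "HB", "HP")
  oral_beneficial <- rbind(
    "Streptococcus sanguinis"    = c( 1.109359234,  0.581684099, -0.821522451, -0.869520881),
    "Schaalia odontolytica"      = c( 0.866037466,  0.849673343, -0.690221094, -1.025489716),
    "Streptococcus parasanguinis"= c( 0.337667371,  1.244063456, -0.581878978, -0.999851848),
    "Streptococcus gordonii"     = c(-0.358857274,  1.492744777, -0.560460981, -0.573426521),
    "Streptococcus salivarius"   = c( 0.491720027,  1.165130406, -0.709880128, -0.946970304),
    "Haemophilus parainfluenzae" = c(-0.776220496, -0.948818830,  0.794166776,  0.930872549),
    "Prevotella melaninogenica"  = c( 0.770450127,  0.826677921, -0.325488334, -1.271639714),
    "Prevotella histicola"       = c( 0.245255701,  1.304474290, -0.638181156, -0.911548835),
    "Porphyromonas pasteri"      = c(-0.780695420, -0.842878657,  1.237271374,  0.386302702))
  oral_harmful <- rbind(
    "Prevotella intermedia"      = c(-1.4985080,  0.4590254,  0.4778640,  0.5616186),
    "Veillonella atypica"        = c(-0.5790756, -1.1098880,  0.7873802,  0.9015834),
    "Fusobacterium periodonticum"= c( 0.5750737,  0.7623781, -1.4412805,  0.1038287),
    "Rothia aeria"               = c(-1.3043268,  1.0787586,  0.3468471, -0.1212790),
    "Rothia mucilaginosa"        = c( 0.2192554, -1.4718224,  0.6508191,  0.6017479))
  gut_beneficial <- rbind(
    "Bifidobacterium animalis"   = c( 1.494121361, -0.560581746, -0.372957869, -0.560581746),
    "Bifidobacterium longum"     = c( 1.197021612, -0.703599839,  0.442619949, -0.936041723),
    "Roseburia hominis"          = c( 0.765535020,  0.087938774,  0.583712049, -1.437185843),
    "Akkermansia muciniphila"    = c( 0.610792400, -0.848966561,  1.088062043, -0.849887882),
    "Bacteroides plebeius"       = c( 1.227955621, -0.638367168,  0.380040967, -0.969629421),
    "Bacteroides coprocola"      = c( 0.887645241, -0.905704780,  0.843182545, -0.825123005),
    "Bacteroides vulgatus"       = c( 0.427038072, -0.883200836,  1.211329198, -0.755166434),
    "Ruminococcus bicirculans"   = c( 0.033982266, -1.045271919,  1.340779079, -0.329489427),
    "Bifidobacterium bifidum"    = c( 1.262130174, -0.747183405,  0.340924182, -0.855870951),
    "Bifidobacterium breve"      = c(-0.351455176, -0.570271686,  1.491998548, -0.570271686))
  gut_harmful <- rbind(
    "Fusobacterium nucleatum"    = c( 0.50000000,  0.50000000, -1.50000000,  0.50000000),
    "Prevotella copri"           = c( 0.79944717, -0.36895163,  0.81724820, -1.24774370),
    "Clostridioides difficile"   = c( 0.50000000,  0.50000000, -1.50000000,  0.50000000),
    "Ruminococcus torques"       = c(-0.72759706,  0.46694355, -0.92290540,  1.18355900),
    "Desulfovibrio piger"        = c( 0.25744044, -1.11941193, -0.37807051,  1.24004200))
  z <- rbind(oral_beneficial, oral_harmful, gut_beneficial, gut_harmful)
  colnames(z) <- types
  panel <- species_panel(
    species = rownames(z),
    role = rep(c("beneficial", "harmful", "beneficial", "harmful"),
               c(nrow(oral_beneficial), nrow(oral_harmful),
                 nrow(gut_beneficial), nrow(gut_harmful))),
    body_site = rep(c("oral", "gut"),
                    c(nrow(oral_beneficial) + nrow(oral_harmful),
                      nrow(gut_beneficial) + nrow(gut_harmful))))
  if (site != "both") {
    keep <- panel$body_site == site
    z <- z[keep, , drop = FALSE]
    panel <- panel[keep, ]
    class(panel) <- c("species_panel", "data.frame")
  }
  list(z = z, panel = panel)
}

#' Published seeded co-occurrence networks (worked example)
#'
#' The published two-level co-occurrence edge lists around the
#' *Streptococcus* (S-type) and *Haemophilus* (H-type) seed genera,
#' re-entered verbatim, as [seed_network] objects.  Used to validate the
#' edge-tallying and export machinery against the published sign counts
#' (S: 5+/1- at level 1, 33+/9- at level 2; H: 3+/2-, 19+/11-).
#'
#' @param type `"S"` or `"H"`.
#' @return A `seed_network` (see [seeded_two_level_network]).
#' @export
network_fixture <- function(type = c("S", "H")) {
  type <- match.arg(type)
  e1 <- function(partner, r) data.frame(
    partner = partner, R = r, sign = ifelse(r > 0, "Positive", "Negative"),
    p = NA_real_, stringsAsFactors = FALSE)
  e2 <- function(parent, partner, r) data.frame(
    parent = parent, partner = partner, R = r,
    sign = ifelse(r > 0, "Positive", "Negative"), p = NA_real_,
    stringsAsFactors = FALSE)
  if (type == "S") {
    seed <- "Streptococcus"
    lvl1 <- e1(c("Granulicatella", "Gemella", "Actinomyces", "Neisseria",
                 "Corynebacterium", "Selenomonas"),
               c(0.562, 0.529, 0.517, 0.357, 0.303, -0.323))
    lvl2 <- rbind(
      e2("Granulicatella", c("Rothia", "Gemella", "Haemophilus", "Neisseria",
                             "Selenomonas"),
         c(0.609, 0.582, 0.359, 0.350, -0.395)),
      e2("Gemella", c("Granulicatella", "Rothia", "Neisseria",
                      "Corynebacterium", "Selenomonas", "Megasphaera"),
         c(0.582, 0.536, 0.372, 0.304, -0.509, -0.387)),
      e2("Actinomyces", c("Rothia", "Leptotrichia", "Neisseria",
                          "Lachnoanaerobaculum", "Stomatobaculum",
                          "Lachnospira", "UCG-002"),
         c(0.621, 0.399, 0.335, 0.330, 0.328, -0.323, -0.303)),
      e2("Neisseria", c("Rothia", "Lachnoanaerobaculum", "Haemophilus",
                        "Gemella", "Granulicatella", "Porphyromonas",
                        "Actinomyces", "Peptostreptococcus", "Leptotrichia"),
         c(0.538, 0.387, 0.378, 0.372, 0.350, 0.338, 0.335, 0.333, 0.323)),
      e2("Corynebacterium", c("Lautropia", "Rothia", "Cardiobacterium",
                              "F0332", "Gemella", "Amnipila"),
         c(0.446, 0.390, 0.374, 0.318, 0.304, -0.302)),
      e2("Selenomonas", c("Alloprevotella", "Atopobium", "Megasphaera",
                          "Prevotella", "TM7x", "Capnocytophaga",
                          "Gemella", "Granulicatella", "Rothia"),
         c(0.388, 0.373, 0.336, 0.331, 0.306, 0.305, -0.509, -0.395, -0.309)))
  } else {
    seed <- "Haemophilus"
    lvl1 <- e1(c("Veillonella", "Megasphaera", "Streptococcus",
                 "Treponema", "Bacteroides"),
               c(0.451, 0.404, 0.377, -0.322, -0.321))
    lvl2 <- rbind(
      e2("Veillonella", c("Fusobacterium", "Leptotrichia", "Prevotella",
                          "Oribacterium", "Lachnoanaerobaculum",
                          "Megasphaera", "Lautropia"),
         c(0.509, 0.466, 0.434, 0.413, 0.393, 0.307, -0.369)),
      e2("Megasphaera", "Veillonella", 0.307),
      e2("Streptococcus", c("Gemella", "Rothia", "Granulicatella",
                            "Lactococcus", "Clostridium-sensu-stricto-1",
                            "Amnipila", "Lachnospiraceae_uncultured",
                            "Dialister", "Selenomonas", "Alloprevotella",
                            "Bacteroides", "Aggregatibacter", "Prevotella",
                            "Lachnoanaerobaculum", "Peptostreptococcus"),
         c(0.810, 0.682, 0.377, 0.357, 0.343, 0.343, 0.304,
           -0.421, -0.419, -0.415, -0.347, -0.347, -0.334, -0.310, -0.301)),
      e2("Treponema", "Lentimicrobium", 0.370),
      e2("Bacteroides", c("[Ruminococcus]-gnavus-group", "Megamonas",
                          "Blautia", "Escherichia-Shigella", "Streptococcus",
                          "TM7x"),
         c(0.441, 0.415, 0.355, 0.329, -0.347, -0.315)))
  }
  structure(list(seed_taxon = seed, level1_edges = lvl1, level2_edges = lvl2,
                 r_cutoff = 0.3, p_cutoff = 0.05),
            class = "seed_network")
}
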