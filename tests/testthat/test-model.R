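# Model definition: molecule types per scenario, construct classes, and the
# rule inventory (including the documented edits between the normal and
# SW480 cells).

test_that("construct classes carry exactly the documented site subsets", {
  expect_setequal(construct_class("A")$present_sites, c("aa15", "r20", "samp"))
  expect_equal(construct_class("A")$r20_site, "r20_3")
  expect_setequal(construct_class("B")$present_sites, c("aa15", "r20"))
  expect_equal(construct_class("B")$r20_site, "r20_1")
  expect_equal(construct_class("C")$present_sites, "aa15")
  expect_equal(construct_class("D")$present_sites, "r20")
  expect_equal(construct_class("D")$r20_site, "r20_1")
  expect_setequal(construct_class("E")$present_sites, c("r20", "samp"))
  expect_equal(construct_class("E")$r20_site, "r20_3")
  expect_equal(construct_class("E", "truncated_r1")$r20_site, "r20_1")
  expect_length(construct_class("F")$present_sites, 0)
  expect_error(construct_class("G"))
})

test_that("molecule types expose the documented sites per scenario", {
  tys <- molecule_types(cell_model("normal"))
  expect_setequal(names(tys), c("BCAT", "AXIN", "GSK3B", "CK1A", "APC"))
  expect_setequal(tys$APC$sites, c("aa15", "r20_3", "samp"))
  expect_equal(tys$APC$states$r20_3, c("u", "p"))
  expect_setequal(tys$BCAT$sites, c("arm34", "arm59", "S45", "S33_37"))
  expect_setequal(tys$AXIN$sites, c("rgs", "bcat", "gid", "ck1"))

  tys <- molecule_types(cell_model("SW480"))
  expect_setequal(tys$APC1338$sites, c("aa15", "r20_1"))

  tys <- molecule_types(cell_model("SW480",
    transfections = list(list(class = "F", dose = 100))))
  expect_length(tys$APC_F$sites, 0)
})

test_that("every interaction of the base model maps to at least one rule", {
  rt <- rule_table(cell_model("normal"))
  binds <- rt$name[rt$kind == "bind"]
  # the six reversible interactions: ARM5-9/15-aa, ARM3-4/phospho-20-aa,
  # ARM3-4/Axin, SAMP/RGS, GSK/GID, CK1a/Axin
  expect_setequal(binds, c("bcat_APC_15aa", "bcat_APC_20aa", "bcat_axin",
                           "APC_axin", "gsk_axin", "ck1a_axin"))
  expect_true(all(paste0(binds, "_rev") %in% rt$name[rt$kind == "unbind"]))
  # the four catalytic interactions plus dephosphorylation counterparts
  expect_true(all(c("phos_bcat_s45", "phos_bcat_s3337", "phos_APC_r20",
                    "dephos_bcat_s45", "dephos_bcat_s3337", "dephos_APC_r20")
                  %in% rt$name))
  expect_true(all(c("bcat_synth", "bcat_deg_slow", "bcat_deg_fast") %in% rt$name))
  # GSK-mediated phosphorylation (and only it) is LiCl-inhibitable
  expect_setequal(rt$name[rt$gsk_mediated],
                  c("phos_bcat_s3337", "phos_APC_r20"))
})

test_that("the SW480 rule set differs from normal by the two documented edits", {
  rn <- rule_table(cell_model("normal"))
  rs <- rule_table(cell_model("SW480"))
  # edit 1: the SAMP<->RGS rule (and its reverse) is removed
  expect_true("APC_axin" %in% rn$name)
  expect_false(any(grepl("axin$", rs$name[grepl("^APC1338", rs$name)])))
  # edit 2: the 20-aa interaction switches from the high-affinity third
  # repeat to the low-affinity first repeat
  expect_equal(rn$kd_param[rn$name == "bcat_APC_20aa"], "KD2_bap_full")
  expect_equal(rs$kd_param[rs$name == "bcat_APC1338_20aa"], "KD2_bap_1338")
  # nothing else differs: remaining rules agree modulo the pool name
  canon <- function(df) {
    df$name <- gsub("APC1338", "APC", df$name)
    df <- df[!grepl("^APC_axin", df$name), ]
    df$kd_param <- sub("KD2_bap_(full|1338)", "KD2_bap", df$kd_param)
    df[order(df$name), c("name", "kind", "rate_param", "gsk_mediated")]
  }
  expect_equal(canon(rn), canon(rs), ignore_attr = TRUE)
})

test_that("mutant, ablation and transfection scenarios edit the inventory as specified", {
  rt <- rule_table(cell_model("normal", s33_37_mutant = TRUE))
  expect_false("phos_bcat_s3337" %in% rt$name)
  # ablation leaves the rules in place (forward rates are zeroed instead)
  cellab <- cell_model("normal", ablations = "apc_axin")
  expect_true("APC_axin" %in% rule_table(cellab)$name)
  expect_error(cell_model("normal", ablations = "nope"), "unknown interface")
  # a transfected class distinct from the endogenous form adds its own rules
  rt <- rule_table(cell_model("SW480",
    transfections = list(list(class = "E", dose = 50))))
  expect_true("bcat_APC_E_20aa" %in% rt$name)
  expect_true("APC_E_axin" %in% rt$name)
  expect_false("bcat_APC_E_15aa" %in% rt$name)
  expect_error(cell_model("SW480",
    transfections = list(list(class = "B", dose = -1))), "dose")
})

test_that("same-class transfections merge into the endogenous pool", {
  cell <- cell_model("normal", transfections = list(list(class = "A", dose = 250)))
  expect_length(cell$pools, 1L)
  expect_equal(cell$pools[[1]]$dose, 350)
  cell <- cell_model("SW480", transfections = list(list(class = "B", dose = 100)))
  expect_equal(cell$pools[[1]]$dose, 200)
})
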