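# Shared builders for small in-code fixtures.

# A hand-written plate for one sample and the calibrator: Ct values are
# specified directly so expectations can be derived by hand.
hand_plate <- function(sample_id, ct_by_assay, cal_ct_by_assay,
                       cal_id = "CAL") {
  row <- function(id, cts) {
    data.frame(sample_id = id, assay = names(cts), replicate = 1L,
               ct = unname(cts), stringsAsFactors = FALSE)
  }
  rbind(row(sample_id, ct_by_assay), row(cal_id, cal_ct_by_assay))
}

# Noise-free plate for a given allele-A fraction, shared default panel.
exact_plate <- function(p, sample_id = "S") {
  simulate_plate(p, assay_panel(), calibrator_spec(), ct_sd = 0,
                 replicates = 2L, sample_id = sample_id)
}

signals_for <- function(plate, sample_id = "S") {
  cal_cts <- plate[plate$sample_id == "CAL", ]
  allele_signals(plate, calibrator_spec(), cal_cts, assay_panel(),
                 sample_id = sample_id)
}

# Published polyploid roster: per-class mean b and configuration (Table-style
# summary used by the calling tests).
published_polyploids <- function() {
  rbind(
    data.frame(b = c(1.30, 1.01, 1.22, 1.17), ploidy = 3, genotype = "AAA"),
    data.frame(b = c(0.69, 0.63, 0.68), ploidy = 3, genotype = "AAa"),
    data.frame(b = c(0.28, 0.32, 0.29, 0.36), ploidy = 3, genotype = "Aaa"),
    data.frame(b = c(0.00, 0.00, 0.00), ploidy = 3, genotype = "aaa"),
    data.frame(b = c(0.26, 0.27), ploidy = 4, genotype = "Aaaa"),
    data.frame(b = c(0.76, 0.78, 0.76), ploidy = 4, genotype = "AAAa"),
    data.frame(b = c(0.58, 0.57), ploidy = 4, genotype = "AAaa"),
    data.frame(b = 1.03, ploidy = 4, genotype = "AAAA")
  )
}

# Published cross records: observed phenotype counts per progeny-ploidy
# class for the eight tetraploid-by-diploid crosses.
published_crosses <- function() {
  df <- read.csv(text = "
cross,female_genotype,male_genotype,progeny_ploidy,observed_red,observed_white
GFxB431,aa,Aaaa,2,4,5
GFxB431,aa,Aaaa,3,5,5
GFxB431,aa,Aaaa,4,2,0
B431xGF,Aaaa,aa,2,0,1
B431xGF,Aaaa,aa,3,20,30
B431xGF,Aaaa,aa,4,0,0
BTZxB432,aa,Aaaa,2,3,2
BTZxB432,aa,Aaaa,3,8,7
BTZxB432,aa,Aaaa,4,0,1
B432xBTZ,Aaaa,aa,2,3,4
B432xBTZ,Aaaa,aa,3,27,19
B432xBTZ,Aaaa,aa,4,1,1
HB1xB456,aa,AAaa,2,2,1
HB1xB456,aa,AAaa,3,10,0
B456xHB1,AAaa,aa,3,66,14
B456xHB1,AAaa,aa,5,3,0
HB1xH424,aa,AAAA,2,1,0
HB1xH424,aa,AAAA,3,4,0
HB1xH424,aa,AAAA,4,5,0
H424xHB1,AAAA,aa,3,5,0
", stringsAsFactors = FALSE)
  df
}
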