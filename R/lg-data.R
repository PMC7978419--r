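# LG amino-acid replacement model constants (Le & Gascuel 2008).
# Residue order used throughout the package:

AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")

# Exchangeabilities: lower triangle, column-wise (R~A, N~A, D~A, ...).
LG_EXCH_LOWER <- c(          0.425093, 0.27681800000000001,           0.395144, 2.4890840000000001, 0.96989400000000003, 1.0385450000000001, 2.0660400000000001, 0.35885800000000001, 0.14982999999999999, 0.39533699999999999, 0.53651800000000005, 1.1240349999999999, 0.25370100000000001,           1.177651,           4.727182, 2.1395010000000001, 0.18071699999999999, 0.21895899999999999, 2.5478700000000001, 0.75187800000000005, 0.12395399999999999,           0.534551, 2.8079079999999998, 0.36397000000000002, 0.39019199999999998, 2.4266009999999998, 0.12699099999999999, 0.30184800000000001, 6.3260670000000001, 0.48413299999999998, 0.052721999999999998, 0.33253300000000002,           0.858151, 0.57898700000000003,           0.593607,            0.31444, 0.17088700000000001,           5.076149, 0.52876800000000002, 1.6957519999999999, 0.54171199999999997, 1.4376450000000001, 4.5092379999999999, 0.19150300000000001, 0.068427000000000002, 2.1450779999999998,           0.371004, 0.089524999999999993, 0.16178699999999999, 4.0083580000000003, 2.0006789999999999,           0.045376, 0.61202500000000004, 0.083687999999999999,           0.062556, 0.52338600000000002, 5.2438700000000003, 0.84492599999999995, 0.92711399999999999,            0.01069, 0.015076000000000001, 0.28295900000000002, 0.025548000000000001, 0.017416000000000001, 0.39445599999999997,           1.240275, 0.42586000000000002,            0.02989,           0.135107, 0.037967000000000001, 0.084807999999999995, 0.0034989999999999999, 0.56926500000000002, 0.64054299999999997,           0.320627, 0.59400699999999995,           0.013266, 0.89368000000000003,           1.105251, 0.075382000000000005,           2.784478, 1.1434800000000001, 0.67012799999999995,           1.165532, 1.9592909999999999, 4.1285910000000001,           0.267959, 4.8135050000000001, 0.072854000000000002,           0.582457, 3.2342939999999998,           1.672569, 0.035854999999999998, 0.62429400000000002, 1.2238279999999999,           1.080136, 0.23619899999999999, 0.25733600000000001, 0.21033199999999999, 0.34884700000000002, 0.42388100000000001, 0.044264999999999999, 0.069672999999999999,           1.807177,           0.173735, 0.018811000000000001, 0.41940899999999998, 0.61197299999999999,           0.604545, 0.077852000000000005,           0.120037,           0.245034, 0.31148399999999998, 0.0087049999999999992, 0.044261000000000002, 0.29663600000000001,           0.139538, 0.089585999999999999,           0.196961, 1.7399899999999999, 0.12983600000000001, 0.26849099999999998, 0.054678999999999998, 0.076701000000000005, 0.10888200000000001,           0.366317, 0.69726399999999999, 0.44247199999999998, 0.68213900000000005, 0.50885100000000005,           0.990012, 0.58426199999999995, 0.59705399999999997, 5.3068340000000003, 0.11901299999999999, 4.1450670000000001, 0.15906899999999999, 4.2736070000000002,           1.112727, 0.078281000000000003, 0.064104999999999995,           1.033739,            0.11166, 0.23252300000000001, 10.649107000000001, 0.13750000000000001, 6.3123579999999997,           2.592692,            0.24906,           0.182287, 0.30293599999999998, 0.61963199999999996, 0.29964800000000003,           1.702745, 0.65660399999999997, 0.023917999999999998,           0.390322, 0.74868299999999999,           1.136863, 0.049905999999999999, 0.13193199999999999, 0.18520200000000001,           1.798853, 0.099848999999999993, 0.34695999999999999, 2.0203660000000001, 0.69617499999999999, 0.48130600000000001, 1.8987179999999999, 0.094464000000000006,           0.361819, 0.16500100000000001, 2.4571209999999999, 7.8039019999999999, 0.65468300000000001, 1.3381320000000001, 0.57146799999999998, 0.095130999999999993, 0.089612999999999998, 0.29650100000000001, 6.4722790000000003,           0.248862, 0.40054699999999999, 0.098368999999999998, 0.14082500000000001,           0.245841,           2.188158,           3.151815, 0.18951000000000001, 0.24931300000000001)

# LG stationary frequencies, same residue order.
LG_FREQS <- c(0.079065920934079076, 0.05594094405905594, 0.04197695802304198, 0.053051946948053055, 0.012936987063012939, 0.040766959233040766, 0.07158592841407159, 0.05733694266305734, 0.022354977645022357, 0.062156937843062157, 0.099080900919099088, 0.064599935400064604, 0.022950977049022953, 0.042301957698042306, 0.044039955960044043, 0.0611969388030612, 0.053286946713053292, 0.012065987934012068, 0.034154965845034156, 0.069146930853069152)

lg_exchangeabilities <- function() {
  m <- matrix(0, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  m[lower.tri(m)] <- LG_EXCH_LOWER
  m + t(m)
}
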