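# BLOSUM62 target (joint) amino-acid pair frequencies, symmetric and
# normalised to sum 1, indexed in aa_alphabet() order. Derived from the
# published integer BLOSUM62 half-bit score matrix by solving the
# self-consistency condition sum_b p(b) * 2^(s(a,b)/2) = 1 for the background
# vector p and setting joint(a,b) = p(a) * p(b) * 2^(s(a,b)/2): rounding the
# half-bit log-odds of this table recovers every one of the 210 published
# integer scores exactly (see the test suite).
.blosum62_joint <- matrix(c(
0.026035029450238934, 0.001742750556414813, 0.0020543953501457098, 0.0027142299402005674, 0.0021542555211452302, 0.0053035409557479832, 0.00093308225422625052, 0.0037246694135086101, 0.0028495548617474349, 0.0050370914282491077, 0.0018755615453346173, 0.0015407890310658143, 0.0025912411244131033, 0.0024698309986432576, 0.0037617495612441982, 0.0065373716082331645, 0.0043288880543809706, 0.0048499575956835184, 0.0003325197891352015, 0.0011624335638055565,
    0.001742750556414813, 0.010558624827856624, 0.00038896110358489934, 0.00025694418380783169, 0.0005768121008368713, 0.00050206284367542418, 0.00017666156775208173, 0.00099729784523732009, 0.00038149089328564614, 0.0013487050446509643, 0.00050219047118337456, 0.00029171941119919326, 0.0003469085310625172, 0.00033065446346914657, 0.00050361311505190862, 0.00087520607798922175, 0.00081959349976531385, 0.00091824821284921068, 0.00012591273061114807, 0.0003112470825492069,
    0.0020543953501457098, 0.00038896110358489934, 0.020750088016385254, 0.0048462695664051227, 0.00096160819094189074, 0.0023673739600453048, 0.00083301124651126933, 0.0011756381591297657, 0.0017988417548435861, 0.0011242186287522082, 0.00059199394031984507, 0.0027510856316592378, 0.0016357757466033561, 0.0022049470874977361, 0.0016791551210422176, 0.002918126482213236, 0.0019323121931934537, 0.0010824525930078145, 0.00014842888865509085, 0.00051888256774059761,
    0.0027142299402005674, 0.00025694418380783169, 0.0048462695664051227, 0.012805607211374049, 0.00089835040832359793, 0.0015638658064404225, 0.0011005593765797419, 0.0010983007738947696, 0.0033610159318431298, 0.0014852972974622668, 0.00078213167544380748, 0.0018173422630107404, 0.0015281689816385557, 0.0041197966802785238, 0.0031373894333187767, 0.0027261624240829496, 0.0018051982752598085, 0.0014301167672430566, 0.00019610156027162449, 0.0006855382537298818,
    0.0021542555211452302, 0.0005768121008368713, 0.00096160819094189074, 0.00089835040832359793, 0.022816358167929436, 0.0012412237069367707, 0.00087350230657682053, 0.0034868387103062456, 0.00094313998076453996, 0.0047154588580858928, 0.0017558016225859153, 0.00072120264129356621, 0.00060644575781491732, 0.00081745973443852538, 0.0012450563617705591, 0.001529985473648513, 0.0014327667282871849, 0.0022701370256700249, 0.00088045388910037927, 0.0043528355388924144,
    0.0053035409557479832, 0.00050206284367542418, 0.0023673739600453048, 0.0015638658064404225, 0.0012412237069367707, 0.034571940667008513, 0.00076030487460426613, 0.0010730268371533377, 0.0016418363624467202, 0.0014511178533331696, 0.00076413337574441145, 0.0025109670787331661, 0.0014930029805847757, 0.0014230497531758032, 0.0021674182515234318, 0.0037666565277644864, 0.0017636573166270784, 0.0013972071294031541, 0.00038317779970763611, 0.00066976274772057758,
    0.00093308225422625052, 0.00017666156775208173, 0.00083301124651126933, 0.0011005593765797419, 0.00087350230657682053, 0.00076030487460426613, 0.0085609458853464632, 0.0005339610526267001, 0.00081701281084320561, 0.00072210721076349958, 0.00038024907442401002, 0.0012495108025706854, 0.00052534508484589559, 0.0010014610862052774, 0.0015253050932251177, 0.00093718433444966325, 0.00062058061148654686, 0.00049163726227531882, 0.00013482931803634229, 0.0013331529441772008,
    0.0037246694135086101, 0.00099729784523732009, 0.0011756381591297657, 0.0010983007738947696, 0.0034868387103062456, 0.0010730268371533377, 0.0005339610526267001, 0.017051687708906201, 0.0011530593865903434, 0.011530004472907503, 0.0030357497221861194, 0.00088172433799612801, 0.0010485339101670077, 0.00099940585615923647, 0.0015221748139759722, 0.0018705220303641475, 0.0024772281454834488, 0.011101651333551532, 0.00026910523410962785, 0.0013304170056324264,
    0.0028495548617474349, 0.00038149089328564614, 0.0017988417548435861, 0.0033610159318431298, 0.00094313998076453996, 0.0016418363624467202, 0.00081701281084320561, 0.0011530593865903434, 0.014114352136704316, 0.0022052547927195595, 0.0011612487471411785, 0.0019079505403431915, 0.0016043597805416553, 0.0030583780734459837, 0.0065876241216673926, 0.0028620822703343627, 0.0018952010828178233, 0.0015014189205586764, 0.00020587870842916599, 0.00071971752831135574,
    0.0050370914282491077, 0.0013487050446509643, 0.0011242186287522082, 0.0014852972974622668, 0.0047154588580858928, 0.0014511178533331696, 0.00072210721076349958, 0.011530004472907503, 0.0022052547927195595, 0.031185418221289885, 0.0058059469461883449, 0.0011924081339651619, 0.001417994615032308, 0.00191138858917261, 0.0029111972400690475, 0.0025296179175866573, 0.0033501025922399673, 0.0075067108732968686, 0.0005146704620488155, 0.0017992018488307241,
    0.0018755615453346173, 0.00050219047118337456, 0.00059199394031984507, 0.00078213167544380748, 0.0017558016225859153, 0.00076413337574441145, 0.00038024907442401002, 0.0030357497221861194, 0.0011612487471411785, 0.0058059469461883449, 0.006114620985736373, 0.00062790134555852368, 0.00074669125562971061, 0.0014234115013035029, 0.0015329857388234, 0.001332052716648123, 0.0012474110673657524, 0.0027951246163492437, 0.0002710164971493897, 0.00066993300559065581,
    0.0015407890310658143, 0.00029171941119919326, 0.0027510856316592378, 0.0018173422630107404, 0.00072120264129356621, 0.0025109670787331661, 0.0012495108025706854, 0.00088172433799612801, 0.0019079505403431915, 0.0011924081339651619, 0.00062790134555852368, 0.011671811160311968, 0.00086749687992525445, 0.0016537022858117676, 0.0025187204515200426, 0.003095125507030852, 0.0020495166310144719, 0.00081183550276089597, 0.00011132112595408305, 0.00055035540109608981,
    0.0025912411244131033, 0.0003469085310625172, 0.0016357757466033561, 0.0015281689816385557, 0.00060644575781491732, 0.0014930029805847757, 0.00052534508484589559, 0.0010485339101670077, 0.0016043597805416553, 0.001417994615032308, 0.00074669125562971061, 0.00086749687992525445, 0.02334277874766472, 0.0013905671977581613, 0.0014976130803261995, 0.0018403393841437505, 0.0017234000477598307, 0.0013653144581107569, 0.00013238148302235163, 0.00046278352182211913,
    0.0024698309986432576, 0.00033065446346914657, 0.0022049470874977361, 0.0041197966802785238, 0.00081745973443852538, 0.0014230497531758032, 0.0010014610862052774, 0.00099940585615923647, 0.0030583780734459837, 0.00191138858917261, 0.0014234115013035029, 0.0016537022858117676, 0.0013905671977581613, 0.010603308008234787, 0.0040374209075059436, 0.0024806890391309189, 0.0016426517860180104, 0.0013013439543575955, 0.00025235775037263212, 0.00088220048461638161,
    0.0037617495612441982, 0.00050361311505190862, 0.0016791551210422176, 0.0031373894333187767, 0.0012450563617705591, 0.0021674182515234318, 0.0015253050932251177, 0.0015221748139759722, 0.0065876241216673926, 0.0029111972400690475, 0.0015329857388234, 0.0025187204515200426, 0.0014976130803261995, 0.0040374209075059436, 0.024597255983444484, 0.0026716525164793979, 0.002501889659140511, 0.0014015214303856305, 0.00027178425356864754, 0.00095011229041041937,
    0.0065373716082331645, 0.00087520607798922175, 0.002918126482213236, 0.0027261624240829496, 0.001529985473648513, 0.0037666565277644864, 0.00093718433444966325, 0.0018705220303641475, 0.0028620822703343627, 0.0025296179175866573, 0.001332052716648123, 0.003095125507030852, 0.0018403393841437505, 0.0024806890391309189, 0.0026716525164793979, 0.013132223299633212, 0.0043479190090441999, 0.0017222573172894294, 0.0002361606792155587, 0.00082557823305867456,
    0.0043288880543809706, 0.00081959349976531385, 0.0019323121931934537, 0.0018051982752598085, 0.0014327667282871849, 0.0017636573166270784, 0.00062058061148654686, 0.0024772281454834488, 0.0018952010828178233, 0.0033501025922399673, 0.0012474110673657524, 0.0020495166310144719, 0.0017234000477598307, 0.0016426517860180104, 0.002501889659140511, 0.0043479190090441999, 0.016286569515174487, 0.0032256423662337672, 0.00031275968521759639, 0.00077311912060436575,
    0.0048499575956835184, 0.00091824821284921068, 0.0010824525930078145, 0.0014301167672430566, 0.0022701370256700249, 0.0013972071294031541, 0.00049163726227531882, 0.011101651333551532, 0.0015014189205586764, 0.0075067108732968686, 0.0027951246163492437, 0.00081183550276089597, 0.0013653144581107569, 0.0013013439543575955, 0.0014015214303856305, 0.0017222573172894294, 0.0032256423662337672, 0.01445565558503327, 0.00024777492648721429, 0.0012249630775803646,
    0.0003325197891352015, 0.00012591273061114807, 0.00014842888865509085, 0.00019610156027162449, 0.00088045388910037927, 0.00038317779970763611, 0.00013482931803634229, 0.00026910523410962785, 0.00020587870842916599, 0.0005146704620488155, 0.0002710164971493897, 0.00011132112595408305, 0.00013238148302235163, 0.00025235775037263212, 0.00027178425356864754, 0.0002361606792155587, 0.00031275968521759639, 0.00024777492648721429, 0.0061502373167548353, 0.00067188127932161818,
    0.0011624335638055565, 0.0003112470825492069, 0.00051888256774059761, 0.0006855382537298818, 0.0043528355388924144, 0.00066976274772057758, 0.0013331529441772008, 0.0013304170056324264, 0.00071971752831135574, 0.0017992018488307241, 0.00066993300559065581, 0.00055035540109608981, 0.00046278352182211913, 0.00088220048461638161, 0.00095011229041041937, 0.00082557823305867456, 0.00077311912060436575, 0.0012249630775803646, 0.00067188127932161818, 0.0093951382804288511
), nrow = 20, byrow = TRUE, dimnames = list(.AA, .AA))

#' BLOSUM62 pair and background frequencies
#'
#' The target (joint) frequency table behind the BLOSUM62 score matrix,
#' together with its background (marginal) residue frequencies. The joint
#' table is symmetric, sums to 1, and reproduces the published integer
#' BLOSUM62 scores when its half-bit log-odds are rounded; the background
#' vector is its row-sum marginal.
#'
#' These are the inputs of \code{\link{blosum62_rate_matrix}}: the
#' substitution model is obtained from the conditional matrix
#' \code{joint[a, b] / background[a]} by a principal matrix logarithm.
#'
#' @return A list with components \code{joint} (20 x 20 symmetric probability
#'   matrix) and \code{background} (named length-20 probability vector), both
#'   in \code{\link{aa_alphabet}} order.
#' @export
#' @examples
#' f <- blosum62_frequencies()
#' sum(f$joint)              # 1
#' f$background[c("H", "D")] # marginal frequencies of His and Asp
blosum62_frequencies <- function() {
  list(joint = .blosum62_joint, background = rowSums(.blosum62_joint))
}
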