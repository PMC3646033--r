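-0.362324556739021753  0.931902965874716882  0.016666666666666670
 0.895661142348604278 -0.441917546706162456  0.050000000000000003
-0.956804953634340039 -0.278531571381673171  0.083333333333333329
 0.515633261582680746  0.848829328215334189  0.116666666666666669
 0.192291730029261004 -0.969806109777801906  0.149999999999999994
-0.792342567994466007  0.581878117678284790  0.183333333333333320
 0.970536405187463869  0.105426001353322557  0.216666666666666674
-0.639148350664171194 -0.727316565082406052  0.250000000000000000
-0.019816572686513427  0.958816732055288279  0.283333333333333326
 0.655043033637138339 -0.686032686033017702  0.316666666666666652
-0.934655928583708606  0.062596287136903059  0.349999999999999978
 0.721209178024010744  0.576986028504578585  0.383333333333333359
-0.139810878133372063 -0.898243734876266409  0.416666666666666741
-0.494780904513270392  0.743432482831514418  0.450000000000000011
 0.849937714858129190 -0.209749302145753408  0.483333333333333337
-0.751505044664705912 -0.410238617634973435  0.516666666666666718
 0.270222441219669152  0.790240363599128304  0.550000000000000155
 0.325360174817969250 -0.744219711419042307  0.583333333333333370
-0.719758428555450247  0.318857376809148108  0.616666666666666696
 0.720247553833906262  0.242370503973305701  0.650000000000000022
-0.352949844001671786 -0.639125936865928779  0.683333333333333348
-0.163791570421644078  0.677909441111200772  0.716666666666666785
 0.548842491692288825 -0.369150266575821284  0.750000000000000000
-0.614665372407206423 -0.092603287481596228  0.783333333333333326
 0.362718726651317547  0.448877133402897144  0.816666666666666652
 0.032636654952004823 -0.525770718805777415  0.849999999999999978
-0.337438593084081029  0.325357369856068002  0.883333333333333304
 0.399522257441609852 -0.010207253841377962  0.916666666666666630
-0.235555259923966392 -0.204972484792843995  0.949999999999999956
 0.020515601734752628  0.180650672960320363  0.983333333333333282
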