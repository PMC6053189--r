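targets, factors
IR, IR
ATM, IR & (!Wip1 | E2F1)
ATR, IR
miR-449a, IR
Sirt-1, E2F1 | !miR-449a
p53-MAIN, (ATM | ATR | E2F1 & 14-3-3s) & !Mdm2
Mdm2, (!Wip1 | p53-MAIN | RB) & !ATM & !ATR
p53-Arrest, (p53-MAIN | !p53-INP1) & !p53-Killer & !Sirt-1
p53-Killer, !p53-Arrest & (!Sirt-1 | !Wip1) & p53-MAIN
p53-INP1, p53-Arrest | p53-Killer
Wip1, p53-Arrest
p21, (p53-Arrest | p53-Killer) & !c-Myc
14-3-3s, p53-Arrest | p53-Killer
c-Myc, (E2F1 | !RB) & !miR-449a
E2F1, !RB & (ATM & ATR & !miR-449a | !Sirt-1) | c-Myc | Cdc25ABC
RB, !Mdm2 & !Cdc25ABC & !Sirt-1
Cdc25ABC, (!miR-449a | c-Myc) & !ATM & !ATR & !14-3-3s
Cdc2-CycB, Cdc25ABC | !p21 & !14-3-3s
Proliferation, !p53-MAIN & (Cdc2-CycB | E2F1)
G2/M-Arrest, p21 | 14-3-3s
G2/M-Apoptosis, p53-Killer
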