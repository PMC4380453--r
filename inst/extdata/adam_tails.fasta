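>ADAM8 cytosolic tail, expressed bait sequence
HIIVYRKARSRILSRNVAPKTTMGRSNPLFHQAASRVPAKGGAPAPSRGPQELVPTTHPG
QPARHPASSVALKRPPPAPPVTVSSPPFPVPVYTRQAPKQVIKPTFAPPVPPVKPGAGAA
NPGPAEGAVGPKVALKPPIQRKQGAGAPTAP*
>ADAM9 cytosolic tail, expressed bait sequence
RDQLWRSYFRKKRSQTYESDGKNQANPSRQPGSVPRHVSPVTPPREVPIYANRFAVPTYA
AKQPQQFPSRPPPPQPKVSSQGNLIPARPAPAPPLYSSLT*
>ADAM10 cytosolic tail, expressed bait sequence
QICSVHTPSSNPKLPPPKPLPGTLKRRRPPQPIQQPQRQRPRESYQMGHMRR*
>ADAM12 cytosolic tail, expressed bait sequence
RKTLIRLLFTNKKTTIEKLRCVRPSRPPRGFQPCQAHLGHLGKGLMRKPPDSYPPKDNPR
RLLQCQNVDISRPLNGLNVPQPQSTQRVLPPLHRAPRAPSVPARPLPAKPALRQAQGTCK
PNPPQKPLPADPLARTTRLTHALARTPGQWETGLRLAPLRPAPQYPHQVPRSTHTAYIK*
>ADAM15 cytosolic tail (isoform 6), expressed bait sequence
MLGASYWYRARLHQRLCQLKGPTCQYRAAQSGPSERPGPPQRALLARGTKQASALSFPAP
PSRPLPPDPVSKRLQAELADRPNPPTRPLPADPVVRSPKSQGPAKPPPPRKPLPADPQGR
CPSGDLPGPGAGIPPLVVPSRPAPPPPTVSSLYL*
>ADAM17 cytosolic tail, expressed bait sequence
HSILVHCVDKKLDKQYESLSLFHPSNVEMLSSMDSASVRIIKPFPAPQTPGRLQPAPVIP
SAPAAPKLDHQRMDTIQEDPSTDSHMDEDGFEKDPFPNSSTAAKSFEDLTDHPVTRSEKA
ASFKLQRQNRGDSKETEC*
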