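>Homo_sapiens
QRHAHNENNSPFMRHCHFGREQAGLGFFDYFDEYAYDWNKHMERQVELYERNYIYQAYIECCDRMRDNIV
QWGIEDWVHILQKGYDVFYFGWRDDYHEELRFNQDEDYGIQGLHIGQADQRYWFGVGVAKFWCNEKGWCF
CDYKWNWCYYNMKYKAHFFIIANEHQDFQEVAIQYDWLVCWACDVVEWWVGHGCNLKDRE----NFLGKQ
EVDVCDWDQNENEKWGQAKVRIKFDYNGYAQKMEAFNCEVWYFRWRQLQRCMMNFKKKEHIERKRIGEIY
LGWRGKWYFHILVMFDVTPFQMCDEISPTPREEFLMNDYHCELHWVKMISPLKSPMELAHTSPCNQYQAC
MKNQFAHDC
>Pan_troglodytes
QRHAHNENNSPFMRHCHFGREQAGLGFFDYFDEYAYDWNKHMERQVELYERNYIYQAYIECCDRMRDNIV
QWGIEDWFHILQKGYDVFYFGIRDDYHEELRFNQDEDYGIQGLHIGQADQRYWFGVGVAKGWCNEKGWCF
CDYKWNWCYYNMKYKAHFFIIANEHQDFQEVAIQYDWLVCWACDVVEWWVGHFCNLKDRE----NFLGKQ
EVDVCDWDQNENEKWGQAKVRIKFDYNGYAQKMEAFNCEVWYFRWRQLQICMMNFKIKEHIERKRIGEIY
LGWRGKWYFHILVMFDVTPFQMFDKFSPTPWHFVACYDGKWDKQDFVANSPEVSPCQDMATSPCCKGFNW
RYIWRVWDM
>Balaena_mysticetus
QRHAHNENNSPFMRHCHFGREQAGLGFFDYFDEYAYDWNKHMERQVELYERNYIYQAYIECCDRMRDNIV
QWGIEDWVHILQKGYDVFYFGWRDDYHEELRFNQDEDYGIQGLHIGQADQNYWFGVGVVKFWCNEKGWCF
CDYKWNWCYYNMKYKAHFFIIANEHQDFQEVAIQYDWLVCWACDVVEWWYGHGCNLKDRE----NFLGKQ
EVDVCDWDQNENEKWGQAKVRIKFMCNGYAQKMEAFNCEVWYFRWRQLQRCMMNFKKKEHIERKRIGEIY
LGWRGKWYFHILVMFDVTPFQMDKLYTPDQRDVTPYQNQHVGWSPVVMHYGVKYQIYKTPNNIHMGGTPI
EWAKDM---
>Tursiops_truncatus
QRHAHNENNSPFMRHCHFGREQAGLGFFDYFDEYAYDWNKHMERQVELYERNYIYHAYIECCDRMRDNIV
QWGIEDWVHGLQKGYDVFYFGWRDDYHEELRFIQDEDYGIQGLHIGQADQRYWFGVGVAKFWCNEKGWCF
CDYKWNWCYYNMKYKAHFFIIANEHQDFQEVAKQYDWLVCWACDVVEWWVGHGCNLKDRE----NFLGWQ
EVDVCDWDQNENEKWGQAKVRIKFDYNGYAQKMEAFNCEVWYFRWRQLQRCMMNFKKKEHIERKRIGEIY
AGWRGKWYFHILVMFDVTPFQMRCILLCTPIFMCLQKMMWRSPDERMRKREWHLCETPDAQHNLHTPGVF
DKVA-----
>Cavia_porcellus
QRHAHNENNSPFMAHCHFGREQAGLGFFDYFDEYAYDWNKHMERQVELYERNYIYQAYIECCDAMRFNIV
QWGIEDWVHILQKGYDVFYFGWRDDYHEELRFNQDEDYGIQGLHIGQADQRYWFGVGVAKFWCNEKAWCF
CDYKWNWCYYNMKYKAHFFIIANEHQDFQEVAIQYDWLVCWADDVVEWWVGHGCNLKDRE----NFLGKQ
EVDVCDWDQNENEKWGQAKVRIKFDYNGYAQKMEAFNCEVWYFRWRQLQRCMMNFKKKLHIERKRIGEIY
LGWRGKWYFHILVMFDVAPFQMGRNACRVFNREGMFMLSPVMARKYLRFALFELGGRLCSPHIRLWVVM-
---------
>Heterocephalus_glaber
QRHAHNENNSPFMRHCHFGREQAGLGFFDYFDEYAYDWNKHMEEQVELYERNYIYQAYIECCDRMRDNIV
QWGIEDWVHINQKGYDVFYFGWRDDYHEELRFNQDEDYGIQGLHIGQADQRYWFGVGVAKFWCNEKFWCF
CDYKWNWCYYNMKYKAHFFIIANEHQDFQEVAIGYDWLVCWACDVVEWWVGHGCNLKDRENYMVNLLGKQ
EVDVCDWDQNENEKWGQAKVRIKFDYNGYAQKMEAFNCEVWYFRWRQLQRCMMNFKKKEHIERKRIGEIY
LGWRGKWYFHILVMFDVAPFQMIKECAGFSPCARCCMFWVVCGRHSPDEMYWDWHFCMKIMTPVDMEKMQ
FV-------
>Mus_musculus
QRCAHNENNSPFMRHCHFGREQAGLGFFDYFDEYAYDWNKHMERQVELYERNYIYQAYIECCDRMRDNIV
QWGIEDWIHILQKGYDVFYFGWRDDYHEELRFNQDEDYGIQGLHIGQADQRYWFGVGVAKFWCNEKGWCF
CDYKWNWCYYNMKYKAHFFIIANEHQDFQEVAIQYDWLVCWACDFVEWWVGHHCNLKDRE----NFLGKQ
EVDVCDWDQNENEKWGQAKVRIKFDYNGYAQKMEAFNCEVWYFRWRQLQRCMMNFKKKEHIERVRIGEIY
DGWRGKWYFHILVMFDVAPFQMLLIDCFHFCTPHNWKHEWRNEHWRHHIMNNWWLHFF------------
---------
>Bos_taurus
QRHAHNENNSPFMRHCHFGREQAGLGFFDYFDEYAYDWNKHMERQVELYERNYIYQAYIECCDRMRDNIV
EWGIEDWVHALQKGYDVFYFGWRDDYHEQLRENQDEDYGIQGLHIGQADQRYWFGVGVAKFWCNEKGWCF
CDYKWNWCYYNMKYKAHFFIIANEHQDFQEVAIQYDWLVFWACDVVEWWVGHGCNLKDRE----NFLGKQ
EVDVCDWDQNENEKWGQIKVRIKFDYNGYAQKMEAFNCEVWYFRWRQLQRCMMNFKKKEHIERKRIGEIY
LGWRGKWYFHILVMFDVAPFQMALQIQGEWGGIGCTPEVRNNDGYVMGGLATPRVGWIMWARVE------
---------
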