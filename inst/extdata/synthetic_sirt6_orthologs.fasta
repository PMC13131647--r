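>Homo_sapiens
QRHAHNENNSPFMRHCHFGREQAGLGFFDYFDEYAYDWNKHMERQVELYERNYIYQAYIECCDRMRDNIV
QWGIEDWVHILQKGYDVFYFGWRDDYHEELRFNQDEDYGIQGLHIGQADQRYWFGVGVAKFWCNEKGWCF
CDYKWNWCYYNMKYKAHFFIIANEHQDFQEVAIQYDWLVCWACDVVEWWVGHGCNLKDRENFLGKQEVDV
CDWDQNENEKWGQAKVRIKFDYNGYAQKMEAFNCEVWYFRWRQLQRCMMNFKKKEHIERKRIGEIYLGWR
GKWYFHILVMFDVTPFQMCDEISPTPREEFLMNDYHCELHWVKMISPLKSPMELAHTSPCNQYQACMKNQ
FAHDC
>Pan_troglodytes
QRHAHNENNSPFMRHCHFGREQAGLGFFDYFDEYAYDWNKHMERQVELYERNYIYQAYIECCDRMRDNIV
QWGIEDWFHILQKGYDVFYFGIRDDYHEELRFNQDEDYGIQGLHIGQADQRYWFGVGVAKGWCNEKGWCF
CDYKWNWCYYNMKYKAHFFIIANEHQDFQEVAIQYDWLVCWACDVVEWWVGHFCNLKDRENFLGKQEVDV
CDWDQNENEKWGQAKVRIKFDYNGYAQKMEAFNCEVWYFRWRQLQICMMNFKIKEHIERKRIGEIYLGWR
GKWYFHILVMFDVTPFQMFDKFSPTPWHFVACYDGKWDKQDFVANSPEVSPCQDMATSPCCKGFNWRYIW
RVWDM
>Balaena_mysticetus
QRHAHNENNSPFMRHCHFGREQAGLGFFDYFDEYAYDWNKHMERQVELYERNYIYQAYIECCDRMRDNIV
QWGIEDWVHILQKGYDVFYFGWRDDYHEELRFNQDEDYGIQGLHIGQADQNYWFGVGVVKFWCNEKGWCF
CDYKWNWCYYNMKYKAHFFIIANEHQDFQEVAIQYDWLVCWACDVVEWWYGHGCNLKDRENFLGKQEVDV
CDWDQNENEKWGQAKVRIKFMCNGYAQKMEAFNCEVWYFRWRQLQRCMMNFKKKEHIERKRIGEIYLGWR
GKWYFHILVMFDVTPFQMDKLYTPDQRDVTPYQNQHVGWSPVVMHYGVKYQIYKTPNNIHMGGTPIEWAK
DM
>Tursiops_truncatus
QRHAHNENNSPFMRHCHFGREQAGLGFFDYFDEYAYDWNKHMERQVELYERNYIYHAYIECCDRMRDNIV
QWGIEDWVHGLQKGYDVFYFGWRDDYHEELRFIQDEDYGIQGLHIGQADQRYWFGVGVAKFWCNEKGWCF
CDYKWNWCYYNMKYKAHFFIIANEHQDFQEVAKQYDWLVCWACDVVEWWVGHGCNLKDRENFLGWQEVDV
CDWDQNENEKWGQAKVRIKFDYNGYAQKMEAFNCEVWYFRWRQLQRCMMNFKKKEHIERKRIGEIYAGWR
GKWYFHILVMFDVTPFQMRCILLCTPIFMCLQKMMWRSPDERMRKREWHLCETPDAQHNLHTPGVFDKVA
>Cavia_porcellus
QRHAHNENNSPFMAHCHFGREQAGLGFFDYFDEYAYDWNKHMERQVELYERNYIYQAYIECCDAMRFNIV
QWGIEDWVHILQKGYDVFYFGWRDDYHEELRFNQDEDYGIQGLHIGQADQRYWFGVGVAKFWCNEKAWCF
CDYKWNWCYYNMKYKAHFFIIANEHQDFQEVAIQYDWLVCWADDVVEWWVGHGCNLKDRENFLGKQEVDV
CDWDQNENEKWGQAKVRIKFDYNGYAQKMEAFNCEVWYFRWRQLQRCMMNFKKKLHIERKRIGEIYLGWR
GKWYFHILVMFDVAPFQMGRNACRVFNREGMFMLSPVMARKYLRFALFELGGRLCSPHIRLWVVM
>Heterocephalus_glaber
QRHAHNENNSPFMRHCHFGREQAGLGFFDYFDEYAYDWNKHMEEQVELYERNYIYQAYIECCDRMRDNIV
QWGIEDWVHINQKGYDVFYFGWRDDYHEELRFNQDEDYGIQGLHIGQADQRYWFGVGVAKFWCNEKFWCF
CDYKWNWCYYNMKYKAHFFIIANEHQDFQEVAIGYDWLVCWACDVVEWWVGHGCNLKDRENYMVNLLGKQ
EVDVCDWDQNENEKWGQAKVRIKFDYNGYAQKMEAFNCEVWYFRWRQLQRCMMNFKKKEHIERKRIGEIY
LGWRGKWYFHILVMFDVAPFQMIKECAGFSPCARCCMFWVVCGRHSPDEMYWDWHFCMKIMTPVDMEKMQ
FV
>Mus_musculus
QRCAHNENNSPFMRHCHFGREQAGLGFFDYFDEYAYDWNKHMERQVELYERNYIYQAYIECCDRMRDNIV
QWGIEDWIHILQKGYDVFYFGWRDDYHEELRFNQDEDYGIQGLHIGQADQRYWFGVGVAKFWCNEKGWCF
CDYKWNWCYYNMKYKAHFFIIANEHQDFQEVAIQYDWLVCWACDFVEWWVGHHCNLKDRENFLGKQEVDV
CDWDQNENEKWGQAKVRIKFDYNGYAQKMEAFNCEVWYFRWRQLQRCMMNFKKKEHIERVRIGEIYDGWR
GKWYFHILVMFDVAPFQMLLIDCFHFCTPHNWKHEWRNEHWRHHIMNNWWLHFF
>Bos_taurus
QRHAHNENNSPFMRHCHFGREQAGLGFFDYFDEYAYDWNKHMERQVELYERNYIYQAYIECCDRMRDNIV
EWGIEDWVHALQKGYDVFYFGWRDDYHEQLRENQDEDYGIQGLHIGQADQRYWFGVGVAKFWCNEKGWCF
CDYKWNWCYYNMKYKAHFFIIANEHQDFQEVAIQYDWLVFWACDVVEWWVGHGCNLKDRENFLGKQEVDV
CDWDQNENEKWGQIKVRIKFDYNGYAQKMEAFNCEVWYFRWRQLQRCMMNFKKKEHIERKRIGEIYLGWR
GKWYFHILVMFDVAPFQMALQIQGEWGGIGCTPEVRNNDGYVMGGLATPRVGWIMWARVE
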