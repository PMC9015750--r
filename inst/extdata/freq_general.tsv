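# General-English frequency table (term TAB count), a small pluggable
# stand-in for a web-scale frequency resource.
the	23135851162
of	13151942776
and	12997637966
to	12136980858
a	9081174698
in	8469404971
for	5933321709
is	4705743816
on	3750423199
that	3400031103
by	3350048871
this	3228469771
with	3183110675
you	3081151934
it	2968800027
not	2285259897
or	2100402500
be	2097419933
are	2064335995
from	1986206494
at	1850210733
as	1833848527
your	1752258047
all	1287213828
have	1231873626
new	1112787319
more	1086857862
an	1070558375
was	1036064548
we	1012284798
will	963307607
home	922930181
can	875003136
us	731470612
about	713661926
if	690304298
page	686213779
my	654508004
has	649128442
search	642201383
free	611959609
but	610839207
our	608815097
one	606974142
other	528421795
do	520023663
no	517066848
information	516196597
time	513390671
they	510360316
site	499596180
he	495077846
up	491961509
may	490428886
what	481351520
which	466205222
their	462949647
news	451855685
out	443097632
use	432625115
any	426497249
there	422160115
see	409912747
only	405988461
so	404442573
his	402790846
when	399823842
contact	395880943
here	391265823
business	387246426
who	379657124
web	374185752
also	372999438
now	371044387
help	361944248
get	358580529
pm	356086391
view	354419575
online	350700153
first	347399722
am	342332044
been	337663643
would	336105244
how	334669310
were	325688682
me	325622054
some	320434821
these	298998096
its	292327766
like	290189329
service	287126483
than	286348124
find	284217595
price	282612584
date	281027567
back	280494353
top	279244717
people	278184619
had	275688898
list	274442736
name	266574379
just	264465044
over	264206791
state	263814888
year	262281364
day	257725351
into	254763441
email	254181518
two	253423430
health	251883346
world	250097784
next	244969170
used	243343817
go	242560087
work	238613084
last	238007322
most	235403649
products	233941202
music	233606403
buy	232602589
data	230284689
make	226608390
them	225253352
should	224420656
product	221624329
system	220858451
post	220619658
her	218998569
city	215940181
add	211536719
policy	210946786
number	210538972
such	209668877
please	207733208
available	205373266
copyright	204864253
support	203739816
message	200066224
after	198658351
best	197577070
software	196953818
then	196228204
good	194014687
video	193283977
well	191313555
where	189501243
info	186534392
rights	185987614
public	183484094
books	182837280
high	182415703
school	181988918
through	181323340
each	179912343
links	178403919
she	178104320
review	177162481
years	176080918
order	175589899
very	173906817
privacy	173146494
book	172921033
items	172854208
company	170044209
read	168978971
group	165663526
need	149936941
many	147135406
user	146067747
said	144673427
does	140730920
set	140331274
under	139959179
general	139075434
research	138724307
university	138460999
january	137967886
mail	136915603
full	136496177
map	135815859
reviews	135588154
program	135252450
life	134376435
know	132993632
games	132976615
way	132879417
days	131677055
part	131294299
could	129553972
great	129038371
united	128933810
real	127959057
item	126567316
international	125459966
center	123878932
must	122541188
store	122413515
travel	121913388
comments	121464886
made	121195442
development	120665997
cold	27489167
pain	24186945
heart	21968097
blood	19767136
fever	9867427
wound	4975737
bone	9057385
operation	8213118
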